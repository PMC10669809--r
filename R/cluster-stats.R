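#' One-way random-effects intraclass correlation
#'
#' ANOVA estimator of the ICC for measurements clustered by animal:
#' `ICC = (MSB - MSW) / (MSB + (m_bar - 1) * MSW)` with `MSB`/`MSW` the
#' between/within-cluster mean squares and `m_bar` the unbalanced-adjusted
#' mean cluster size `(N - sum(m_i^2) / N) / (k - 1)` (which reduces to the
#' common size for balanced designs). Negative estimates are reported
#' as-is; they are clipped only when fed into the design-effect formula.
#'
#' @param values numeric measurements (e.g. per-ROI mean Z-scores).
#' @param cluster cluster identity per value (e.g. animal ID); >= 2
#'   clusters and >= 2 within-cluster residual degrees of freedom required.
#' @return list with `icc`, `k` (clusters), `n` (total), `m_bar`, `msb`,
#'   `msw`.
#' @export
icc_oneway <- function(values, cluster) {
  stopifnot(length(values) == length(cluster))
  ok <- !is.na(values)
  values <- values[ok]; cluster <- factor(cluster[ok])
  k <- nlevels(cluster)
  n <- length(values)
  if (k < 2) stop("need >= 2 clusters to estimate an ICC")
  if (n - k < 2) stop("need >= 2 within-cluster residual degrees of freedom")
  mi <- as.numeric(table(cluster))
  mu_i <- tapply(values, cluster, mean)
  mu <- mean(values)
  ssb <- sum(mi * (mu_i - mu)^2)
  ssw <- sum((values - mu_i[cluster])^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  m_bar <- (n - sum(mi^2) / n) / (k - 1)
  icc <- if (msb == 0 && msw == 0) 0 else (msb - msw) / (msb + (m_bar - 1) * msw)
  list(icc = icc, k = k, n = n, m_bar = m_bar, msb = msb, msw = msw)
}

#' Design-effect effective sample size
#'
#' The theoretical sample size if the measurements were unclustered:
#' `n_eff = n_total / (1 + (m_bar - 1) * icc)`. The ICC is clipped to
#' `[0, 1]` first (the design effect is undefined for negative
#' clustering). `n_eff` never exceeds `n_total` and approaches the number
#' of clusters as the ICC approaches 1 in balanced designs.
#'
#' @param n_total total number of measurements.
#' @param m_bar mean cluster size (>= 1).
#' @param icc intraclass correlation estimate.
#' @return scalar `n_eff`.
#' @export
effective_sample_size <- function(n_total, m_bar, icc) {
  if (m_bar < 1) stop("mean cluster size must be >= 1")
  stopifnot(n_total >= 1)
  icc <- min(max(icc, 0), 1)
  n_total / (1 + (m_bar - 1) * icc)
}

#' ICC and effective sample size from a clustered sample
#'
#' Convenience wrapper chaining [icc_oneway()] and
#' [effective_sample_size()].
#'
#' @inheritParams icc_oneway
#' @return list with `icc`, `n`, `k`, `m_bar`, `n_eff`.
#' @export
neff_from_sample <- function(values, cluster) {
  est <- icc_oneway(values, cluster)
  list(icc = est$icc, n = est$n, k = est$k, m_bar = est$m_bar,
       n_eff = effective_sample_size(est$n, est$m_bar, est$icc))
}

#' Group comparison with animal-level random intercepts
#'
#' Thin delegation layer over [nlme::lme()] for the mixed-effects
#' comparisons used on clustered ROI data: fixed effects of interest
#' (substance, sex, genotype, ...) with random intercepts per cluster
#' (animal identity, optionally nested). Reports Wald F tests
#' (marginal ANOVA) and, when the focal fixed effect has more than two
#' levels, Tukey-adjusted pairwise contrasts via [emmeans::emmeans()].
#' Singular or non-converging fits raise the underlying error rather
#' than being masked.
#'
#' @param data data.frame with the response, grouping and cluster columns.
#' @param fixed fixed-effects formula, e.g. `value ~ group`.
#' @param random random-effects formula, e.g. `~ 1 | cluster` (nested:
#'   `~ 1 | animal / roi`).
#' @param adjust p-value adjustment for pairwise contrasts
#'   (default `"tukey"`).
#' @return list of class `lme_report`: `model` (the `lme` fit),
#'   `coefficients` (fixed effects table), `wald_f` (marginal ANOVA
#'   table), `pairwise` (emmeans contrast data.frame, or `NULL`),
#'   `spec` (deparsed formulas for the record).
#' @export
fit_group_comparison <- function(data, fixed, random = ~ 1 | cluster,
                                 adjust = "tukey") {
  fit <- nlme::lme(fixed = fixed, random = random, data = data,
                   method = "REML")
  wald <- stats::anova(fit, type = "marginal")
  term <- attr(stats::terms(fixed), "term.labels")[1]
  pw <- NULL
  if (!is.null(term) && !is.na(term)) {
    xvals <- data[[term]]
    if ((is.factor(xvals) || is.character(xvals)) &&
        length(unique(xvals)) > 2) {
      em <- emmeans::emmeans(fit, stats::as.formula(paste("~", term)),
                             data = data)
      pw <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                            adjust = adjust))
    }
  }
  structure(list(model = fit,
                 coefficients = summary(fit)$tTable,
                 wald_f = wald,
                 pairwise = pw,
                 spec = list(fixed = deparse(fixed),
                             random = deparse(random))),
            class = "lme_report")
}

#' @export
print.lme_report <- function(x, ...) {
  cat("Mixed-effects comparison:", x$spec$fixed, "| random:",
      x$spec$random, "\n\nWald F (marginal):\n")
  print(x$wald_f)
  if (!is.null(x$pairwise)) {
    cat("\nPairwise contrasts (adjusted):\n")
    print(x$pairwise)
  }
  invisible(x)
}

#' Simulate clustered measurements with known ICC
#'
#' One-way random-effects draw: each value is a cluster effect (variance
#' `icc_true * total_var`) plus residual noise (variance
#' `(1 - icc_true) * total_var`), so the population ICC equals
#' `icc_true` exactly.
#'
#' @param k_clusters number of clusters (>= 2).
#' @param m_per_cluster values per cluster (>= 2).
#' @param icc_true population ICC in `[0, 1]`.
#' @param mu grand mean.
#' @param total_var total variance (default 1).
#' @param seed integer seed.
#' @return list of class `clustered_sample`: `values`, `cluster`
#'   (factor), `icc_true`.
#' @export
generate_clustered_values <- function(k_clusters, m_per_cluster, icc_true,
                                      mu = 0, total_var = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(k_clusters >= 2, m_per_cluster >= 2)
  if (icc_true < 0 || icc_true > 1) stop("icc_true must be in [0, 1]")
  sb <- sqrt(icc_true * total_var)
  sw <- sqrt((1 - icc_true) * total_var)
  b <- stats::rnorm(k_clusters, 0, sb)
  values <- mu + rep(b, each = m_per_cluster) +
    stats::rnorm(k_clusters * m_per_cluster, 0, sw)
  structure(list(values = values,
                 cluster = factor(rep(seq_len(k_clusters),
                                      each = m_per_cluster)),
                 icc_true = icc_true),
            class = "clustered_sample")
}
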