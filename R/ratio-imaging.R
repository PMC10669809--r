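#' Y/C ratio of a two-channel recording
#'
#' Element-wise YFP/CFP ratio per ROI. The ratio, not either raw channel, is
#' the calcium readout of the FRET sensor: a calcium rise moves the
#' channels in opposite directions while gain and bleach move them together.
#'
#' @param rec a `yc_recording` (see [generate_yc_recording()]), or a list
#'   with numeric `yfp` and `cfp` entries of identical shape.
#' @return numeric vector or matrix of the same shape as the channels.
#' @export
compute_yc_ratio <- function(rec) {
  yfp <- rec$yfp
  cfp <- rec$cfp
  stopifnot(length(yfp) == length(cfp))
  bad <- which(cfp <= 0)
  if (length(bad)) {
    i <- bad[1]
    if (is.matrix(cfp)) {
      fr <- (i - 1) %% nrow(cfp) + 1
      roi <- colnames(cfp)[(i - 1) %/% nrow(cfp) + 1] %||% ((i - 1) %/% nrow(cfp) + 1)
      stop("non-positive CFP at ROI ", roi, ", frame ", fr)
    }
    stop("non-positive CFP at frame ", i)
  }
  yfp / cfp
}

#' Baseline windows for the standard response summaries
#'
#' @param which `"screening"` (mean over the 5 min after onset) or
#'   `"receptor_id"` (mean over 10-11 min after onset).
#' @return numeric `c(start, end)` in seconds relative to application onset,
#'   half-open.
#' @export
response_window <- function(which = c("screening", "receptor_id")) {
  switch(match.arg(which),
         screening = c(0, 300),
         receptor_id = c(600, 660))
}

#' Detrend and Z-score a ratio trace against a pre-application baseline
#'
#' Fits a linear trend to the ratio over the baseline window, removes it
#' from the whole segment, and converts to Z using the baseline mean and SD
#' of the detrended trace. This is the `Z_YC` trace used throughout the
#' screening analysis. The detrend is a strategy hook: `"ls"` (default,
#' ordinary least squares) or `"rlm"` (Huber M-estimation via
#' [MASS::rlm()], resistant to baseline transients but undefined on
#' zero-noise baselines).
#'
#' @param ratio numeric vector, or frames x ROIs matrix, of Y/C ratios for
#'   one substance session segment. Time of frame `i` is
#'   `(i - 1) * frame_interval` from the segment start.
#' @param baseline_window `c(start, end)` seconds, half-open, within the
#'   segment and before the application onset; must contain >= 30 samples.
#' @param frame_interval seconds per frame.
#' @param method detrend strategy, `"ls"` or `"rlm"`.
#' @return an object of class `zscore_trace`: list with `z` (same shape as
#'   `ratio`), `ratio_raw`, `baseline_window`, `frame_interval`, `method`.
#' @export
correct_and_zscore <- function(ratio, baseline_window, frame_interval,
                               method = c("ls", "rlm")) {
  method <- match.arg(method)
  m <- if (is.matrix(ratio)) ratio else matrix(ratio, ncol = 1)
  n <- nrow(m)
  t <- (seq_len(n) - 1) * frame_interval
  base <- which(t >= baseline_window[1] & t < baseline_window[2])
  if (length(base) < 30) {
    stop("baseline window holds ", length(base), " samples; need >= 30")
  }
  z <- m
  for (j in seq_len(ncol(m))) {
    fit <- switch(method,
      ls = stats::lm.fit(cbind(1, t[base]), m[base, j]),
      rlm = MASS::rlm(cbind(1, t[base]), m[base, j], maxit = 50))
    co <- stats::coef(fit)
    detr <- m[, j] - (co[1] + co[2] * t)
    mu <- mean(detr[base])
    sdv <- stats::sd(detr[base])
    if (sdv <= 1e-10 * mean(abs(m[base, j]))) {
      stop("baseline SD is zero (constant trace) in column ", j)
    }
    z[, j] <- (detr - mu) / sdv
  }
  structure(list(
    z = if (is.matrix(ratio)) z else drop(z),
    ratio_raw = ratio,
    baseline_window = baseline_window,
    frame_interval = frame_interval,
    method = method
  ), class = "zscore_trace")
}

#' Mean Z-score over a response window
#'
#' Arithmetic mean of `Z_YC` over the half-open window
#' `[onset + window[1], onset + window[2])`. With the default
#' `window = response_window("screening")` this is the 5-min post-onset
#' mean used for substance classification; `response_window("receptor_id")`
#' gives the 10-11 min mean used for genotype comparison.
#'
#' @param zt a `zscore_trace`, or a numeric vector/matrix of Z values (then
#'   `frame_interval` must be given).
#' @param onset application onset, seconds from segment start.
#' @param window `c(start, end)` seconds relative to onset, half-open.
#' @param frame_interval seconds per frame (taken from `zt` if it is a
#'   `zscore_trace`).
#' @return scalar (vector input) or named vector over ROIs (matrix input).
#' @export
mean_response <- function(zt, onset, window = response_window("screening"),
                          frame_interval = NULL) {
  if (inherits(zt, "zscore_trace")) {
    frame_interval <- zt$frame_interval
    zt <- zt$z
  }
  stopifnot(!is.null(frame_interval))
  m <- if (is.matrix(zt)) zt else matrix(zt, ncol = 1)
  n <- nrow(m)
  idx <- frames_in_window(n, frame_interval, onset + window[1], onset + window[2])
  if (!length(idx) || (onset + window[2]) > n * frame_interval + 1e-9) {
    stop("response window [", onset + window[1], ", ", onset + window[2],
         ") extends past the recording end (", n * frame_interval, " s)")
  }
  out <- colMeans(m[idx, , drop = FALSE])
  if (is.matrix(zt)) out else unname(out)
}

#' Classify a substance from pooled per-ROI mean Z-scores
#'
#' Quartiles of the pooled mean Z-scores are computed by linear
#' interpolation of order statistics at positions `p * (n - 1)`
#' ([stats::quantile()] type 7). A substance is called `"increase"` when the
#' third quartile exceeds 2, `"decrease"` when the first quartile is below
#' -2, and `"none"` otherwise. The +/-2 cut was calibrated against
#' glutamate, GABA and aCSF controls and is deliberately conservative.
#'
#' @param values numeric vector of per-ROI mean Z-scores pooled across
#'   slices; at least 4 values.
#' @param threshold classification cut in Z units (default 2).
#' @return list with `classification` (one of `"increase"`, `"decrease"`,
#'   `"none"`) and `quartiles` (named `q1`, `median`, `q3`).
#' @export
classify_substance <- function(values, threshold = 2) {
  values <- values[!is.na(values)]
  if (length(values) < 4) stop("need >= 4 values to classify; got ", length(values))
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  inc <- q[3] > threshold
  dec <- q[1] < -threshold
  if (inc && dec) {
    stop("both quartile criteria met (Q1 = ", signif(q[1], 4), ", Q3 = ",
         signif(q[3], 4), "): bimodal response, not classifiable")
  }
  list(classification = if (inc) "increase" else if (dec) "decrease" else "none",
       quartiles = c(q1 = q[1], median = q[2], q3 = q[3]))
}

#' FWHM of a suppression transient
#'
#' Duration statistic for calcium-decrease responses. The minimum of the
#' `ma_frames`-frame moving average of `Z_YC` (`z_min120` for the default
#' 120 frames) sets the half-maximum level; the FWHM is the span between
#' the first and last frames at which the raw `Z_YC` is strictly below half
#' that minimum. ROIs whose 5-min post-onset mean Z is not less than
#' `exclude_if_mean_above` (-2 by default) did not show a clear decrease
#' and are excluded. The moving average is centered with truncated edges;
#' comparisons use strict `<`.
#'
#' @param zt a `zscore_trace` or numeric Z vector (then supply
#'   `frame_interval`).
#' @param onset application onset, seconds from segment start (used for the
#'   exclusion window).
#' @param ma_frames moving-average width in frames (default 120).
#' @param exclude_if_mean_above exclusion cut on the 5-min mean Z
#'   (default -2: mean >= -2 excludes the ROI).
#' @param frame_interval seconds per frame if `zt` is a bare vector.
#' @return a one-row data.frame: `z_min120`, `t_from`, `t_to` (1-based
#'   frame indices), `fwhm_frames`, `fwhm_seconds`, `excluded`, `censored`
#'   (`TRUE` when a crossing touches the recording edge). For excluded ROIs
#'   the numeric fields are `NA`.
#' @export
fwhm <- function(zt, onset, ma_frames = 120, exclude_if_mean_above = -2,
                 frame_interval = NULL) {
  if (inherits(zt, "zscore_trace")) {
    frame_interval <- zt$frame_interval
    z <- zt$z
  } else z <- zt
  stopifnot(!is.null(frame_interval), is.numeric(z), !is.matrix(z))
  n <- length(z)
  if (n <= ma_frames) stop("recording (", n, " frames) not longer than ma_frames")
  mz <- mean_response(z, onset, response_window("screening"),
                      frame_interval = frame_interval)
  if (mz >= exclude_if_mean_above) {
    return(data.frame(z_min120 = NA_real_, t_from = NA_integer_,
                      t_to = NA_integer_, fwhm_frames = NA_integer_,
                      fwhm_seconds = NA_real_, excluded = TRUE,
                      censored = NA))
  }
  zmin <- min(moving_average_centered(z, ma_frames))
  if (zmin >= 0) {
    stop("smoothed minimum is non-negative for a non-excluded ROI; ",
         "inconsistent trace")
  }
  below <- which(z < 0.5 * zmin)
  t_from <- below[1]
  t_to <- below[length(below)]
  data.frame(z_min120 = zmin, t_from = t_from, t_to = t_to,
             fwhm_frames = t_to - t_from,
             fwhm_seconds = (t_to - t_from) * frame_interval,
             excluded = FALSE,
             censored = t_from == 1L || t_to == n)
}

#' Peak dR/R0 for stimulus-evoked ratio transients
#'
#' Electrophysiological-confirmation metric on the raw (uncorrected) Y/C
#' ratio: the peak ratio inside the stimulation window minus the mean ratio
#' over the `baseline_duration` seconds immediately preceding it (`R0`),
#' divided by `R0`. Scale-invariant by construction.
#'
#' @param ratio numeric Y/C ratio vector.
#' @param stim_window `c(start, end)` seconds, half-open, of the current
#'   injection.
#' @param frame_interval seconds per frame.
#' @param baseline_duration pre-stimulus baseline length, seconds
#'   (default 30; at least this much pre-stimulus data is required).
#' @return scalar peak dR/R0.
#' @export
peak_dr_over_r0 <- function(ratio, stim_window, frame_interval,
                            baseline_duration = 30) {
  n <- length(ratio)
  if (stim_window[1] < baseline_duration - 1e-9) {
    stop("need >= ", baseline_duration, " s of pre-stimulus data")
  }
  base <- frames_in_window(n, frame_interval,
                           stim_window[1] - baseline_duration, stim_window[1])
  stim <- frames_in_window(n, frame_interval, stim_window[1], stim_window[2])
  stopifnot(length(base) > 0, length(stim) > 0)
  r0 <- mean(ratio[base])
  if (r0 <= 0) stop("baseline ratio R0 is non-positive")
  (max(ratio[stim]) - r0) / r0
}

#' Analyze one screening session: per-substance Z-scoring and summaries
#'
#' For every annotated application the segment from 5 min before onset to
#' the start of the next application's baseline (or the recording end) is
#' detrended and Z-scored against the 5-min pre-onset baseline, and the
#' windowed mean Z is computed per ROI. Applications whose baseline would
#' start before the recording (or overlap the previous application) are
#' flagged and their means set `NA`, never silently dropped.
#'
#' @param rec a `yc_recording`.
#' @param window response window passed to [mean_response()].
#' @param baseline_duration pre-onset baseline length, seconds (default 300).
#' @param method detrend strategy, see [correct_and_zscore()].
#' @return object of class `screen_summary`: list with `roi_means` (tidy
#'   data.frame: substance, roi, mean_z, flagged) and `classification`
#'   (data.frame: substance, classification, q1, median, q3 — from this
#'   recording's ROIs alone; use [screen_cohort()] to pool slices).
#' @export
screen_session <- function(rec, window = response_window("screening"),
                           baseline_duration = 300, method = "ls") {
  ratio <- compute_yc_ratio(rec)
  n <- nrow(ratio)
  dt <- rec$frame_interval
  apps <- rec$applications
  apps <- apps[order(apps$onset), ]
  out <- vector("list", nrow(apps))
  for (j in seq_len(nrow(apps))) {
    onset <- apps$onset[j]
    seg_start <- onset - baseline_duration
    prev_end <- if (j > 1) apps$onset[j - 1] + apps$duration[j - 1] else 0
    seg_end <- if (j < nrow(apps)) apps$onset[j + 1] - baseline_duration else n * dt
    flagged <- seg_start < prev_end - 1e-9 || seg_start < 0 ||
      (onset + window[2]) > seg_end + 1e-9
    if (flagged) {
      out[[j]] <- data.frame(substance = apps$substance[j],
                             roi = colnames(ratio) %||% seq_len(ncol(ratio)),
                             mean_z = NA_real_, flagged = TRUE)
      next
    }
    idx <- frames_in_window(n, dt, seg_start, seg_end)
    zt <- correct_and_zscore(ratio[idx, , drop = FALSE],
                             baseline_window = c(0, baseline_duration),
                             frame_interval = dt, method = method)
    mz <- mean_response(zt, onset = baseline_duration, window = window)
    out[[j]] <- data.frame(substance = apps$substance[j],
                           roi = names(mz) %||% seq_along(mz),
                           mean_z = unname(mz), flagged = FALSE)
  }
  roi_means <- do.call(rbind, out)
  structure(list(roi_means = roi_means,
                 classification = classify_table(roi_means)),
            class = "screen_summary")
}

#' Pool screening sessions across slices and classify substances
#'
#' @param summaries list of `screen_summary` objects (one per slice), or a
#'   single tidy `roi_means`-style data.frame.
#' @return data.frame: substance, classification, q1, median, q3, n.
#' @export
screen_cohort <- function(summaries) {
  if (is.data.frame(summaries)) {
    pooled <- summaries
  } else {
    pooled <- do.call(rbind, lapply(summaries, function(s) s$roi_means))
  }
  classify_table(pooled)
}

classify_table <- function(roi_means) {
  ok <- roi_means[!roi_means$flagged & !is.na(roi_means$mean_z), ]
  res <- lapply(split(ok$mean_z, ok$substance), function(v) {
    cl <- classify_substance(v)
    data.frame(classification = cl$classification,
               q1 = cl$quartiles[["q1"]], median = cl$quartiles[["median"]],
               q3 = cl$quartiles[["q3"]], n = length(v))
  })
  cbind(data.frame(substance = names(res)),
        do.call(rbind, unname(res)))
}
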