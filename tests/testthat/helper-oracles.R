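# Independent oracles, written as plain loops so they share no code path
# with the implementation they check.

# Exhaustive threshold-scan FWHM: explicit windowed means and a linear
# scan for the first/last strict crossings.
naive_fwhm <- function(z, onset, ma_frames = 120, frame_interval = 1,
                       exclude_if_mean_above = -2) {
  n <- length(z)
  t <- (seq_len(n) - 1) * frame_interval
  win <- z[t >= onset & t < onset + 300]
  if (mean(win) >= exclude_if_mean_above) return(list(excluded = TRUE))
  sm <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - ma_frames %/% 2L)
    hi <- min(n, i + (ma_frames + 1L) %/% 2L - 1L)
    sm[i] <- sum(z[lo:hi]) / (hi - lo + 1L)
  }
  zmin <- min(sm)
  thr <- 0.5 * zmin
  t_from <- NA_integer_; t_to <- NA_integer_
  for (i in seq_len(n)) if (z[i] < thr) { t_from <- i; break }
  for (i in rev(seq_len(n))) if (z[i] < thr) { t_to <- i; break }
  list(excluded = FALSE, z_min120 = zmin, t_from = t_from, t_to = t_to,
       fwhm_frames = t_to - t_from)
}

# Brute-force one-way ICC from explicit sums of squares.
naive_icc <- function(values, cluster) {
  cl <- split(values, cluster)
  k <- length(cl)
  n <- length(values)
  mu <- mean(values)
  ssb <- 0; ssw <- 0
  for (g in cl) {
    ssb <- ssb + length(g) * (mean(g) - mu)^2
    for (v in g) ssw <- ssw + (v - mean(g))^2
  }
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  m_bar <- (n - sum(vapply(cl, length, 0L)^2) / n) / (k - 1)
  (msb - msw) / (msb + (m_bar - 1) * msw)
}

# Direct windowed mean (trailing, truncated start) for the smoothing check.
naive_trailing_ma <- function(x, k) {
  out <- numeric(length(x))
  for (i in seq_along(x)) out[i] <- mean(x[max(1, i - k + 1):i])
  out
}

# Linear-interpolation quantile at position p * (n - 1), from scratch.
naive_quantile <- function(x, p) {
  x <- sort(x)
  h <- p * (length(x) - 1)
  lo <- floor(h) + 1
  x[lo] + (h - floor(h)) * (x[min(lo + 1, length(x))] - x[lo])
}

# One synthetic screening cohort -> pooled classification.
run_screen_cohort <- function(direction, depth, responder_fraction, seed,
                              n_slices = 2, n_rois = 12) {
  eff <- list(substance_effect("X", direction, depth = depth,
                               duration_fwhm = 300,
                               responder_fraction = responder_fraction))
  sums <- lapply(seq_len(n_slices), function(s) {
    rec <- generate_yc_recording(eff, onsets = 400, n_rois = n_rois,
                                 frame_interval = 1, session_duration = 1000,
                                 seed = seed * 10 + s,
                                 slice_id = paste0("s", s))
    screen_session(rec)
  })
  screen_cohort(sums)$classification
}
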