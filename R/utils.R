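#' Centered moving average with edge truncation
#'
#' Moving average over a window of `k` samples centered on each point. Near
#' the edges the window is truncated to the available samples, so the output
#' has the same length as the input and no NA padding. For even `k` the
#' window extends one sample further into the past than into the future.
#'
#' @param x numeric vector.
#' @param k integer window width in samples (>= 1).
#' @return numeric vector of `length(x)`.
#' @export
moving_average_centered <- function(x, k) {
  stopifnot(is.numeric(x), length(x) >= 1, k >= 1)
  k <- as.integer(k)
  n <- length(x)
  # window [i - floor(k/2), i + ceil(k/2) - 1], clipped to [1, n]
  lo <- pmax(seq_len(n) - k %/% 2L, 1L)
  hi <- pmin(seq_len(n) + (k + 1L) %/% 2L - 1L, n)
  cs <- cumsum(c(0, x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Trailing moving average with truncated start
#'
#' Mean of the current sample and the `k - 1` preceding samples; at the start
#' of the series the window is truncated (partial means), so no samples are
#' lost.
#'
#' @inheritParams moving_average_centered
#' @return numeric vector of `length(x)`.
#' @export
moving_average_trailing <- function(x, k) {
  stopifnot(is.numeric(x), length(x) >= 1, k >= 1)
  k <- as.integer(k)
  n <- length(x)
  lo <- pmax(seq_len(n) - k + 1L, 1L)
  cs <- cumsum(c(0, x))
  (cs[seq_len(n) + 1L] - cs[lo]) / (seq_len(n) - lo + 1L)
}

# Frame indices (1-based) whose times fall in the half-open window
# [t_start, t_end). Frame i corresponds to time (i - 1) * frame_interval.
frames_in_window <- function(n, frame_interval, t_start, t_end) {
  t <- (seq_len(n) - 1) * frame_interval
  which(t >= t_start & t < t_end)
}

# Run-length intervals of a logical mask: data.frame(start, end, value)
# with 1-based inclusive frame indices.
mask_runs <- function(mask) {
  stopifnot(is.logical(mask), length(mask) >= 1)
  r <- rle(mask)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  data.frame(start = start, end = end, value = r$values)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
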