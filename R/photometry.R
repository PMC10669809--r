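#' Construct a raw PMT stream object
#'
#' Wraps a 1 kHz photometry voltage series with its interleaving layout:
#' each 50-point cycle (50 ms) holds a 25-point burst of one excitation
#' channel followed by a 25-point burst of the other, reflecting LEDs
#' alternating at 20 Hz with 25-ms illumination.
#'
#' @param voltage numeric PMT voltage series sampled at 1 kHz (1 point =
#'   1 ms). Length must be a multiple of `cycle_points`.
#' @param points_per_burst samples per LED burst (default 25).
#' @param cycle_points samples per full 470+405 cycle (default 50).
#' @param first_channel which channel the first burst belongs to, `"470"`
#'   or `"405"`.
#' @return object of class `raw_pmt_stream`.
#' @export
raw_pmt_stream <- function(voltage, points_per_burst = 25, cycle_points = 50,
                           first_channel = c("470", "405")) {
  first_channel <- match.arg(first_channel)
  stopifnot(is.numeric(voltage), cycle_points == 2 * points_per_burst)
  if (length(voltage) %% cycle_points != 0) {
    stop("stream length (", length(voltage),
         ") is not a multiple of cycle_points (", cycle_points, ")")
  }
  structure(list(voltage = voltage, points_per_burst = points_per_burst,
                 cycle_points = cycle_points, first_channel = first_channel),
            class = "raw_pmt_stream")
}

#' De-interleave a raw PMT stream into 20 Hz channel series
#'
#' For every burst, the mean of its 13th-24th samples (1-based, inclusive;
#' 12 samples) becomes one 20 Hz data point — the early samples and the
#' last sample of each burst are discarded as LED settling/transition
#' points. Returns the calcium-dependent 470-nm and isosbestic 405-nm
#' series.
#'
#' @param raw a [raw_pmt_stream()].
#' @param keep_points burst sample indices averaged per point
#'   (default `13:24`).
#' @return list with numeric `f470` and `f405`, each of length
#'   `length(voltage) / cycle_points`.
#' @export
deinterleave <- function(raw, keep_points = 13:24) {
  stopifnot(inherits(raw, "raw_pmt_stream"))
  ppb <- raw$points_per_burst
  stopifnot(all(keep_points >= 1), all(keep_points <= ppb))
  m <- matrix(raw$voltage, nrow = raw$cycle_points)
  first <- colMeans(m[keep_points, , drop = FALSE])
  second <- colMeans(m[ppb + keep_points, , drop = FALSE])
  if (raw$first_channel == "470") {
    list(f470 = first, f405 = second)
  } else {
    list(f470 = second, f405 = first)
  }
}

#' Isosbestic correction of the 470-nm signal
#'
#' Removes the calcium-independent (motion/artifact) component using the
#' 405-nm isosbestic channel: `F_GC = F470 - F405 * mu470 / mu405`, where
#' `mu470` and `mu405` are the means of the first third of each series.
#' The scaling by the ratio of first-third means puts the 405 channel on
#' the 470 channel's scale, so artifact components shared proportionally
#' by both channels cancel. The means are taken over the full series'
#' first third (the correction is defined on the whole recording, before
#' any behavioral windowing).
#'
#' @param f470,f405 20 Hz channel series of equal length.
#' @return numeric `F_GC` series.
#' @export
isosbestic_correct <- function(f470, f405) {
  stopifnot(length(f470) == length(f405))
  n3 <- floor(length(f470) / 3)
  if (n3 < 1) stop("series too short: first third is empty")
  mu470 <- mean(f470[seq_len(n3)])
  mu405 <- mean(f405[seq_len(n3)])
  if (mu405 == 0) stop("mean of the first third of F405 is zero")
  f470 - f405 * (mu470 / mu405)
}

#' Smooth and min-max normalize the corrected signal over a test window
#'
#' `F_TS` is the 10-point moving average of `F_GC` restricted to the
#' behavioral-test window (trailing window, truncated at the start);
#' `F_TSre = (F_TS - min) / (max - min)` rescales it to attain 0 and 1
#' within the window.
#'
#' @param f_gc corrected 20 Hz series from [isosbestic_correct()].
#' @param window `c(first, last)` 1-based sample indices of the test
#'   window (default: the whole series). Must span >= `k` points.
#' @param k moving-average width in samples (default 10).
#' @param align `"trailing"` (default) or `"centered"` moving average.
#' @return list with `f_ts`, `f_tsre` (same length as the window) and
#'   `window` (the indices used).
#' @export
smooth_and_normalize <- function(f_gc, window = NULL, k = 10,
                                 align = c("trailing", "centered")) {
  align <- match.arg(align)
  window <- window %||% c(1L, length(f_gc))
  idx <- seq.int(window[1], window[2])
  if (length(idx) < k) stop("window holds fewer than ", k, " points")
  f_ts <- switch(align,
                 trailing = moving_average_trailing(f_gc[idx], k),
                 centered = moving_average_centered(f_gc[idx], k))
  rng <- range(f_ts)
  if (rng[1] == rng[2]) stop("F_TS is constant; cannot min-max normalize")
  list(f_ts = f_ts, f_tsre = (f_ts - rng[1]) / (rng[2] - rng[1]),
       window = window)
}

#' Per-epoch normalization and immobility-onset value
#'
#' For each mobile-immobile epoch, the epoch's signal is rescaled by its
#' mobile-period maximum (`F_Emax` -> 1) and immobile-period minimum
#' (`F_Emin` -> 0): `F_Enorm = (F_E - F_Emin) / (F_Emax - F_Emin)`.
#' `F_Eonset` is `F_Enorm` at the first immobile sample; a low value
#' means the calcium signal had already fallen near its immobile floor
#' when the animal stopped moving. Values of `F_Enorm` outside `[0, 1]`
#' can occur away from the two anchor samples and are legitimate. Epochs
#' with `F_Emax <= F_Emin` are flagged invalid and excluded from the
#' mean.
#'
#' @param f_tsre normalized 20 Hz series (see [smooth_and_normalize()]).
#' @param epochs data.frame with 1-based inclusive sample indices
#'   `mobile_start`, `mobile_end`, `immobile_start`, `immobile_end`
#'   (as produced by [score_immobility()], resampled to the photometry
#'   rate if needed).
#' @return list with `epochs` (data.frame adding `f_emax`, `f_emin`,
#'   `f_eonset`, `valid`), `f_enorm` (list of per-epoch normalized
#'   series), and `mean_f_eonset` (mean over valid epochs).
#' @export
epoch_normalize <- function(f_tsre, epochs) {
  stopifnot(is.data.frame(epochs), nrow(epochs) >= 1)
  n <- length(f_tsre)
  if (any(epochs$immobile_end > n) || any(epochs$mobile_start < 1)) {
    stop("epoch indices fall outside the series")
  }
  res <- epochs
  res$f_emax <- NA_real_; res$f_emin <- NA_real_
  res$f_eonset <- NA_real_; res$valid <- FALSE
  f_enorm <- vector("list", nrow(epochs))
  for (i in seq_len(nrow(epochs))) {
    mob <- seq.int(epochs$mobile_start[i], epochs$mobile_end[i])
    imm <- seq.int(epochs$immobile_start[i], epochs$immobile_end[i])
    emax <- max(f_tsre[mob]); emin <- min(f_tsre[imm])
    res$f_emax[i] <- emax; res$f_emin[i] <- emin
    if (emax > emin) {
      res$valid[i] <- TRUE
      seg <- seq.int(epochs$mobile_start[i], epochs$immobile_end[i])
      f_enorm[[i]] <- (f_tsre[seg] - emin) / (emax - emin)
      res$f_eonset[i] <- (f_tsre[epochs$immobile_start[i]] - emin) / (emax - emin)
    }
  }
  if (!any(res$valid)) stop("no valid epochs (all have F_Emax <= F_Emin)")
  list(epochs = res, f_enorm = f_enorm,
       mean_f_eonset = mean(res$f_eonset[res$valid]))
}

#' Simulate a raw interleaved photometry stream
#'
#' Forward model of the acquisition: a 20 Hz latent calcium signal and a
#' 20 Hz shared motion artifact are encoded into 25-point LED bursts at
#' 1 kHz. The 470-nm channel carries latent + artifact, the 405-nm
#' channel the artifact only, both as multiplicative modulations of the
#' channel operating points (defaults -1 V and -0.5 V): `V470 = v470 *
#' (1 + gain * (latent + artifact))`, `V405 = v405 * (1 + gain *
#' artifact)`. An optional LED-settling transient is added to the first
#' `settle_points` samples of each burst, and white sample noise on top.
#' With `settle_amp = 0` and `noise_sd = 0`, bursts are constant and
#' [deinterleave()] recovers the encoded 20 Hz values exactly.
#'
#' @param latent numeric 20 Hz latent calcium series.
#' @param artifact numeric 20 Hz shared artifact series (default 0).
#' @param v470,v405 channel operating points, volts.
#' @param gain relative modulation per unit signal (default 0.05).
#' @param settle_amp LED settling transient amplitude, volts
#'   (default 0.02).
#' @param settle_points number of early burst samples carrying the
#'   settling transient (default 12 — exactly the samples the analysis
#'   discards).
#' @param noise_sd white noise SD per 1 kHz sample, volts
#'   (default 0.002).
#' @param first_channel which channel is pulsed first (default `"470"`).
#' @param seed integer seed.
#' @return list of class `photometry_sim`: `raw` (a [raw_pmt_stream()]),
#'   and `truth` (list with the clean 20 Hz `f470`, `f405`, the encoded
#'   `latent`, `artifact`, and `f_gc_expected = v470 * gain * latent`,
#'   the corrected signal the chain should recover when the latent mean
#'   over the first third is zero).
#' @export
generate_photometry_raw <- function(latent, artifact = NULL,
                                    v470 = -1, v405 = -0.5, gain = 0.05,
                                    settle_amp = 0.02, settle_points = 12,
                                    noise_sd = 0.002,
                                    first_channel = "470", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(latent)
  artifact <- artifact %||% rep(0, n)
  stopifnot(length(artifact) == n, n >= 1)
  f470 <- v470 * (1 + gain * (latent + artifact))
  f405 <- v405 * (1 + gain * artifact)
  ppb <- 25L
  burst <- function(values) {
    m <- matrix(rep(values, each = ppb), nrow = ppb)
    if (settle_amp > 0 && settle_points > 0) {
      m[seq_len(settle_points), ] <- m[seq_len(settle_points), ] +
        settle_amp * exp(-(seq_len(settle_points) - 1) / 3)
    }
    m
  }
  b1 <- burst(if (first_channel == "470") f470 else f405)
  b2 <- burst(if (first_channel == "470") f405 else f470)
  voltage <- as.numeric(rbind(b1, b2))
  if (noise_sd > 0) voltage <- voltage + stats::rnorm(length(voltage), 0, noise_sd)
  structure(list(
    raw = raw_pmt_stream(voltage, points_per_burst = ppb,
                         cycle_points = 2L * ppb,
                         first_channel = first_channel),
    truth = list(f470 = f470, f405 = f405, latent = latent,
                 artifact = artifact,
                 f_gc_expected = v470 * gain * latent)
  ), class = "photometry_sim")
}
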