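#' Per-epoch features for vigilance staging
#'
#' Splits EEG/EMG/IR-activity signals into fixed epochs (default 4 s) and
#' computes the staging features: EEG band amplitudes as the RMS of the
#' band-passed signal per epoch for the delta (1.5-4 Hz) and theta
#' (5-8 Hz) bands, their ratio (`theta_ratio`), the RMS of the band-passed
#' EMG, and the summed IR activity counts. Band-pass filtering uses
#' zero-phase 4th-order Butterworth filters consistent with the
#' acquisition filters (EEG 1.5-30 Hz, EMG 15-300 Hz); if the sampling
#' rate cannot support the EMG upper edge it is capped at `0.45 *
#' sample_rate`. A trailing partial epoch is dropped with a warning.
#'
#' @param eeg,emg,ir numeric series of equal length, or an `eeg_recording`
#'   from [generate_eeg_emg()] passed as `eeg`.
#' @param sample_rate Hz (>= 100).
#' @param epoch_length seconds per epoch (default 4).
#' @param delta_band,theta_band EEG bands, Hz.
#' @param emg_band EMG band, Hz (upper edge capped below Nyquist).
#' @return data.frame of class `epoch_features`: `epoch`, `ir_activity`,
#'   `emg_rms`, `delta_amp`, `theta_amp`, `theta_ratio`.
#' @export
epoch_features <- function(eeg, emg = NULL, ir = NULL, sample_rate = NULL,
                           epoch_length = 4,
                           delta_band = c(1.5, 4), theta_band = c(5, 8),
                           emg_band = c(15, 300)) {
  if (is.list(eeg)) {
    rec <- eeg
    eeg <- rec$eeg; emg <- rec$emg; ir <- rec$ir
    sample_rate <- rec$sample_rate %||% sample_rate
    epoch_length <- rec$epoch_length %||% epoch_length
  }
  stopifnot(!is.null(sample_rate), length(emg) == length(eeg),
            length(ir) == length(eeg))
  if (sample_rate < 100) stop("sample_rate must be >= 100 Hz")
  if (max(theta_band) >= sample_rate / 2) {
    stop("sample_rate too low for the theta band")
  }
  spe <- epoch_length * sample_rate
  if (abs(spe - round(spe)) > 1e-9) {
    stop("epoch_length * sample_rate must be an integer number of samples")
  }
  spe <- as.integer(round(spe))
  n_ep <- length(eeg) %/% spe
  if (n_ep < 1) stop("signals shorter than one epoch")
  if (length(eeg) %% spe != 0) {
    warning("dropping trailing partial epoch (",
            length(eeg) - n_ep * spe, " samples)")
  }
  keep <- seq_len(n_ep * spe)
  emg_band[2] <- min(emg_band[2], 0.45 * sample_rate)

  band_rms <- function(x, band) {
    b <- signal::butter(4, band / (sample_rate / 2), type = "pass")
    xf <- signal::filtfilt(b, x)
    sqrt(colMeans(matrix(xf[keep]^2, nrow = spe)))
  }
  delta_amp <- band_rms(eeg, delta_band)
  theta_amp <- band_rms(eeg, theta_band)
  out <- data.frame(
    epoch = seq_len(n_ep),
    ir_activity = colSums(matrix(ir[keep], nrow = spe)),
    emg_rms = band_rms(emg, emg_band),
    delta_amp = delta_amp,
    theta_amp = theta_amp,
    theta_ratio = theta_amp / delta_amp
  )
  class(out) <- c("epoch_features", "data.frame")
  out
}

#' Staging thresholds
#'
#' The staging rules compare features against "higher" thresholds that are
#' resolved per recording: IR activity and EMG RMS against their 75th
#' percentile, delta amplitude against its 60th percentile, and the theta
#' ratio against a fixed cut of 1 (a ratio above 1 means theta dominates
#' delta regardless of gain). Any threshold can instead be fixed to an
#' absolute value.
#'
#' @param ir_pct,emg_pct,delta_pct percentiles in `[0, 1]` used to resolve
#'   the respective thresholds from the recording.
#' @param theta_ratio_cut absolute theta-ratio cut (default 1).
#' @param ir_abs,emg_abs,delta_abs optional absolute overrides.
#' @return a `stage_thresholds` specification list.
#' @export
stage_thresholds <- function(ir_pct = 0.75, emg_pct = 0.75, delta_pct = 0.60,
                             theta_ratio_cut = 1,
                             ir_abs = NULL, emg_abs = NULL, delta_abs = NULL) {
  structure(list(ir_pct = ir_pct, emg_pct = emg_pct, delta_pct = delta_pct,
                 theta_ratio_cut = theta_ratio_cut,
                 ir_abs = ir_abs, emg_abs = emg_abs, delta_abs = delta_abs),
            class = "stage_thresholds")
}

#' Stage epochs into W / NR / R by the rule cascade
#'
#' Applies the automatic screening rules in fixed order as a first-match
#' cascade per epoch: higher IR activity means wakefulness (W); else
#' higher EMG means W; else higher EEG delta amplitude means non-REM (NR);
#' else higher theta ratio means REM (R); otherwise the epoch keeps the
#' previous epoch's state (the first epoch falls back to
#' `initial_state`). Manual rescoring is represented only by the
#' `provenance` field of the result.
#'
#' @param features an `epoch_features` data.frame.
#' @param thresholds a [stage_thresholds()] specification.
#' @param initial_state state assumed before the first epoch (default
#'   `"W"`: recordings start with handling-induced wakefulness).
#' @param epoch_length seconds per epoch, stored on the result.
#' @return object of class `hypnogram`: list with `labels` (character,
#'   one of `"W"`, `"NR"`, `"R"` per epoch), `epoch_length`,
#'   `provenance` (all `"auto"`), and `thresholds` (resolved numeric).
#' @export
stage_epochs <- function(features, thresholds = stage_thresholds(),
                         initial_state = "W", epoch_length = 4) {
  if (nrow(features) == 0) stop("empty feature list")
  thr <- list(
    ir = thresholds$ir_abs %||%
      unname(stats::quantile(features$ir_activity, thresholds$ir_pct, type = 7)),
    emg = thresholds$emg_abs %||%
      unname(stats::quantile(features$emg_rms, thresholds$emg_pct, type = 7)),
    delta = thresholds$delta_abs %||%
      unname(stats::quantile(features$delta_amp, thresholds$delta_pct, type = 7)),
    theta_ratio = thresholds$theta_ratio_cut
  )
  labels <- character(nrow(features))
  prev <- initial_state
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    labels[i] <-
      if (f$ir_activity > thr$ir) "W"
      else if (f$emg_rms > thr$emg) "W"
      else if (f$delta_amp > thr$delta) "NR"
      else if (f$theta_ratio > thr$theta_ratio) "R"
      else prev
    prev <- labels[i]
  }
  structure(list(labels = labels, epoch_length = epoch_length,
                 provenance = rep("auto", length(labels)),
                 thresholds = thr),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c("W", "NR", "R")))
  cat("Hypnogram:", length(x$labels), "epochs x", x$epoch_length, "s\n")
  cat(sprintf("  %s: %d epochs (%.1f%%)\n", names(tab), as.integer(tab),
              100 * as.integer(tab) / length(x$labels)), sep = "")
  invisible(x)
}

#' Per-state durations by schedule period
#'
#' Sums vigilance-state durations (label count x epoch length) within each
#' schedule period, e.g. the light and dark phases of a 12/12 cycle. The
#' schedule must tile the recording without gaps; per period the three
#' state totals sum exactly to the period duration.
#'
#' @param h a `hypnogram`.
#' @param schedule data.frame with `period` (label), `start`, `end`
#'   (seconds, half-open, from recording start). An epoch belongs to the
#'   period containing its start time.
#' @return data.frame: `period`, `state`, `seconds`.
#' @export
state_durations <- function(h, schedule) {
  stopifnot(inherits(h, "hypnogram"), is.data.frame(schedule))
  L <- h$epoch_length
  total <- length(h$labels) * L
  sch <- schedule[order(schedule$start), ]
  if (sch$start[1] > 0 || sch$end[nrow(sch)] < total ||
      (nrow(sch) > 1 && any(sch$start[-1] != sch$end[-nrow(sch)]))) {
    stop("schedule has gaps or does not cover the recording (0-", total, " s)")
  }
  t0 <- (seq_along(h$labels) - 1) * L
  per <- sch$period[findInterval(t0, sch$start)]
  out <- expand.grid(period = unique(sch$period),
                     state = c("W", "NR", "R"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$seconds <- mapply(function(p, s) sum(per == p & h$labels == s) * L,
                        out$period, out$state)
  out[order(match(out$period, unique(sch$period))), ]
}

#' Simulate EEG/EMG/IR signals for a vigilance-state sequence
#'
#' Per-state spectral construction: the EEG is a sum of delta-band
#' (1.5-4 Hz) and theta-band (5-8 Hz) filtered noise plus a broadband
#' (1.5-30 Hz) floor, with state-dependent band gains — NR elevates delta,
#' R elevates theta relative to delta; the EMG is band-limited noise with
#' an elevated gain in W; IR activity is a sparse event train with a high
#' event rate in W. Per-epoch lognormal gain jitter (`jitter_sdlog`)
#' emulates within-state amplitude variability. Ground-truth labels are
#' attached.
#'
#' @param state_sequence character vector of `"W"`, `"NR"`, `"R"` epoch
#'   labels.
#' @param epoch_length seconds per epoch (default 4).
#' @param sample_rate Hz (default 250; >= 100).
#' @param gains named list of per-state band gains; see defaults in the
#'   function signature.
#' @param ir_rate named per-state mean IR events per epoch.
#' @param jitter_sdlog lognormal SD of the per-epoch gain jitter
#'   (default 0.2).
#' @param seed integer seed.
#' @return list of class `eeg_recording`: `eeg`, `emg`, `ir`,
#'   `sample_rate`, `epoch_length`, `truth` (list with `labels`).
#' @export
generate_eeg_emg <- function(state_sequence, epoch_length = 4,
                             sample_rate = 250,
                             gains = list(
                               delta = c(W = 1, NR = 3, R = 0.8),
                               theta = c(W = 0.6, NR = 0.8, R = 2),
                               emg = c(W = 3, NR = 1, R = 0.5)),
                             ir_rate = c(W = 8, NR = 0.3, R = 0.1),
                             jitter_sdlog = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bad <- setdiff(unique(state_sequence), c("W", "NR", "R"))
  if (length(bad)) stop("unknown state label(s): ", paste(bad, collapse = ", "))
  if (sample_rate < 100) stop("sample_rate must be >= 100 Hz")
  spe <- as.integer(round(epoch_length * sample_rate))
  n_ep <- length(state_sequence)
  n <- n_ep * spe
  nyq <- sample_rate / 2

  band_noise <- function(band) {
    b <- signal::butter(4, pmin(band, 0.45 * sample_rate) / nyq, type = "pass")
    x <- signal::filtfilt(b, stats::rnorm(n))
    x / stats::sd(x)
  }
  per_sample_gain <- function(g) {
    jit <- stats::rlnorm(n_ep, 0, jitter_sdlog)
    rep(unname(g[state_sequence]) * jit, each = spe)
  }
  eeg <- per_sample_gain(gains$delta) * band_noise(c(1.5, 4)) +
    per_sample_gain(gains$theta) * band_noise(c(5, 8)) +
    0.5 * band_noise(c(1.5, 30))
  emg <- per_sample_gain(gains$emg) * band_noise(c(15, 300))
  p_event <- rep(unname(ir_rate[state_sequence]) / spe, each = spe)
  ir <- as.numeric(stats::runif(n) < p_event)

  structure(list(eeg = eeg, emg = emg, ir = ir,
                 sample_rate = sample_rate, epoch_length = epoch_length,
                 truth = list(labels = state_sequence)),
            class = "eeg_recording")
}

#' Sample a plausible vigilance-state sequence with persistent bouts
#'
#' First-order Markov chain over W/NR/R with transition probabilities
#' tuned to rodent-like bout durations (mean W and NR bouts of minutes, R
#' bouts shorter, R entered from NR only). Handy as input to
#' [generate_eeg_emg()].
#'
#' @param n_epochs number of 4-s epochs.
#' @param p_stay named per-state probability of remaining in the state per
#'   epoch.
#' @param seed integer seed.
#' @return character vector of labels, starting in `"W"`.
#' @export
simulate_state_sequence <- function(n_epochs,
                                    p_stay = c(W = 0.98, NR = 0.97, R = 0.92),
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- character(n_epochs)
  s <- "W"
  for (i in seq_len(n_epochs)) {
    labels[i] <- s
    if (stats::runif(1) >= p_stay[[s]]) {
      s <- switch(s,
                  W = "NR",
                  NR = if (stats::runif(1) < 0.25) "R" else "W",
                  R = "W")
    }
  }
  labels
}
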