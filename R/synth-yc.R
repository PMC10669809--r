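#' Describe a substance effect for the slice-imaging simulator
#'
#' @param name substance label (e.g. `"Glu"`, `"GABA"`, `"aCSF"`).
#' @param direction one of `"increase"`, `"decrease"`, `"none"`: the sign of
#'   the intracellular-calcium change the substance evokes.
#' @param depth peak response amplitude in Z units of the baseline ratio
#'   noise (>= 0; ignored for `"none"`).
#' @param onset_delay seconds between application onset and response start.
#' @param duration_fwhm response full width at half maximum, seconds.
#' @param responder_fraction fraction of ROIs that respond, in `[0, 1]`.
#' @return an object of class `substance_effect`.
#' @seealso [generate_yc_recording()]
#' @export
substance_effect <- function(name, direction = c("none", "increase", "decrease"),
                             depth = 0, onset_delay = 0,
                             duration_fwhm = 300, responder_fraction = 1) {
  direction <- match.arg(direction)
  stopifnot(depth >= 0, duration_fwhm > 0,
            responder_fraction >= 0, responder_fraction <= 1)
  structure(list(name = name, direction = direction, depth = depth,
                 onset_delay = onset_delay, duration_fwhm = duration_fwhm,
                 responder_fraction = responder_fraction),
            class = "substance_effect")
}

#' Simulate a ratiometric (YFP/CFP) slice-imaging session
#'
#' Generates per-ROI two-channel fluorescence traces for a sequential
#' substance-screening session, with ground truth attached. The FRET sensor
#' contract is honored: during a calcium increase YFP rises while CFP falls
#' (and vice versa), so the Y/C ratio carries the response while
#' channel-common bleaching cancels. Specifically, for latent relative ratio
#' modulation `s(t)`, `YFP = Y0 * sqrt(1 + s) * bleach * (1 + noise)` and
#' `CFP = C0 / sqrt(1 + s) * bleach * (1 + noise)`, giving
#' `Y/C = (Y0/C0) * (1 + s)` before noise.
#'
#' Response depth is specified in Z units of the baseline ratio noise: with
#' independent relative channel noise of SD `noise_sd`, the relative SD of
#' the ratio is `sqrt(2) * noise_sd` to first order, and the generator
#' scales the kernel so a downstream baseline Z-score reaches `depth` at the
#' kernel peak. With `noise_sd = 0` the modulation amplitude is zero (Z
#' units are undefined without noise) and only `"none"` effects are
#' meaningful.
#'
#' @param effects list of [substance_effect()] objects, in application order.
#' @param onsets numeric vector of application onset times (seconds), one
#'   per effect. Each application lasts `application_duration` seconds;
#'   application windows must not overlap.
#' @param n_rois number of ROIs (>= 1).
#' @param frame_interval acquisition frame interval, seconds. Acquisition
#'   rates are instrument-specific, so this is a required parameter with
#'   no default.
#' @param session_duration total session length, seconds; default runs
#'   `600` s past the last onset.
#' @param noise_sd relative (multiplicative) channel noise SD; default 0.01.
#' @param bleach_tau time constant (s) of the shared single-exponential
#'   bleach applied to both channels; default 3600.
#' @param application_duration perfusion application duration, seconds
#'   (default 120, i.e. the 2-min application protocol).
#' @param yfp0,cfp0 baseline channel intensities (a.u.).
#' @param amplitude_jitter per-responder multiplicative jitter half-range on
#'   `depth` (default 0.1, i.e. U(0.9, 1.1)).
#' @param animal_id,slice_id,sex metadata labels.
#' @param seed integer; set for reproducibility (same seed, same output).
#' @return an object of class `yc_recording`: list with matrices `yfp`,
#'   `cfp` (frames x ROIs), `frame_interval`, `applications` data frame
#'   (substance, onset, duration), metadata labels, and `truth`, a list with
#'   `responders` (ROIs x effects logical matrix), `z_expected` (frames x
#'   effects matrix of the signed noiseless Z-unit kernel at unit
#'   responder amplitude times depth), and the per-effect parameters.
#' @export
generate_yc_recording <- function(effects, onsets, n_rois, frame_interval,
                                  session_duration = NULL,
                                  noise_sd = 0.01, bleach_tau = 3600,
                                  application_duration = 120,
                                  yfp0 = 1000, cfp0 = 800,
                                  amplitude_jitter = 0.1,
                                  animal_id = "sim01", slice_id = "s1",
                                  sex = "f", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(effects, "substance_effect")) effects <- list(effects)
  stopifnot(length(effects) == length(onsets), n_rois >= 1,
            frame_interval > 0)
  ord <- order(onsets)
  win <- cbind(onsets[ord], onsets[ord] + application_duration)
  if (length(onsets) > 1 && any(win[-1, 1] < win[-nrow(win), 2])) {
    stop("overlapping application windows")
  }
  session_duration <- session_duration %||% (max(onsets) + 600)
  if (any(onsets + application_duration > session_duration)) {
    stop("application times do not fit inside the session")
  }
  n_frames <- floor(session_duration / frame_interval)
  t <- (seq_len(n_frames) - 1) * frame_interval

  z_unit <- sqrt(2) * noise_sd   # ratio Z unit per unit relative modulation
  z_expected <- matrix(0, n_frames, length(effects))
  responders <- matrix(FALSE, n_rois, length(effects))
  s <- matrix(0, n_frames, n_rois)  # latent relative ratio modulation
  for (j in seq_along(effects)) {
    e <- effects[[j]]
    stopifnot(inherits(e, "substance_effect"))
    if (e$direction == "none" || e$depth == 0) next
    sign_j <- if (e$direction == "increase") 1 else -1
    k <- response_kernel(t, onset = onsets[j], onset_delay = e$onset_delay,
                         duration_fwhm = e$duration_fwhm)
    z_expected[, j] <- sign_j * e$depth * k
    n_resp <- round(e$responder_fraction * n_rois)
    if (n_resp == 0) next
    idx <- sample.int(n_rois, n_resp)
    responders[idx, j] <- TRUE
    amp <- stats::runif(n_resp, 1 - amplitude_jitter, 1 + amplitude_jitter)
    s[, idx] <- s[, idx] +
      outer(sign_j * e$depth * z_unit * k, amp)
  }
  if (any(s <= -1)) {
    stop("response modulation reached -100%; reduce depth or noise_sd")
  }

  bleach <- exp(-t / bleach_tau)
  y0 <- yfp0 * stats::runif(n_rois, 0.8, 1.2)
  c0 <- cfp0 * stats::runif(n_rois, 0.8, 1.2)
  yfp <- sweep(sqrt(1 + s), 2, y0, "*") * bleach
  cfp <- sweep(1 / sqrt(1 + s), 2, c0, "*") * bleach
  if (noise_sd > 0) {
    yfp <- yfp * (1 + matrix(stats::rnorm(n_frames * n_rois, 0, noise_sd),
                             n_frames, n_rois))
    cfp <- cfp * (1 + matrix(stats::rnorm(n_frames * n_rois, 0, noise_sd),
                             n_frames, n_rois))
  }
  colnames(yfp) <- colnames(cfp) <- sprintf("roi%03d", seq_len(n_rois))

  applications <- data.frame(
    substance = vapply(effects, `[[`, "", "name"),
    onset = onsets,
    duration = application_duration
  )
  structure(list(
    yfp = yfp, cfp = cfp, frame_interval = frame_interval,
    applications = applications,
    animal_id = animal_id, slice_id = slice_id, sex = sex,
    truth = list(
      responders = responders,
      z_expected = z_expected,
      direction = vapply(effects, `[[`, "", "direction"),
      depth = vapply(effects, `[[`, 0, "depth"),
      duration_fwhm = vapply(effects, `[[`, 0, "duration_fwhm")
    )
  ), class = "yc_recording")
}

#' @export
print.yc_recording <- function(x, ...) {
  cat("Ratiometric YC recording:", ncol(x$yfp), "ROIs x",
      nrow(x$yfp), "frames @", x$frame_interval, "s\n")
  cat("Applications:", paste(x$applications$substance, collapse = ", "), "\n")
  invisible(x)
}
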