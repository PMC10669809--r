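test_that("YC generator: null effect and determinism", {
  eff <- list(substance_effect("aCSF", "none"))
  rec0 <- generate_yc_recording(eff, onsets = 400, n_rois = 3,
                                frame_interval = 1, noise_sd = 0, seed = 1)
  ratio <- compute_yc_ratio(rec0)
  # no effect, no noise: Y/C constant per ROI over the whole session
  expect_lt(max(apply(ratio, 2, function(r) diff(range(r)))), 1e-12)

  a <- generate_yc_recording(eff, onsets = 400, n_rois = 5,
                             frame_interval = 1, seed = 42)
  b <- generate_yc_recording(eff, onsets = 400, n_rois = 5,
                             frame_interval = 1, seed = 42)
  expect_identical(a$yfp, b$yfp)
  expect_identical(a$cfp, b$cfp)
})

test_that("YC generator: channels move anti-correlated during a response", {
  eff <- list(substance_effect("Glu", "increase", depth = 10,
                               duration_fwhm = 300))
  rec <- generate_yc_recording(eff, onsets = 400, n_rois = 1,
                               frame_interval = 1, noise_sd = 0.005,
                               bleach_tau = Inf, seed = 7)
  base <- 1:300
  resp <- 460:520  # around the kernel peak
  dy <- mean(rec$yfp[resp, 1]) - mean(rec$yfp[base, 1])
  dc <- mean(rec$cfp[resp, 1]) - mean(rec$cfp[base, 1])
  expect_gt(dy, 0)
  expect_lt(dc, 0)
})

test_that("YC generator: deep decrease is recovered by the Z/FWHM chain", {
  eff <- list(substance_effect("PGE2", "decrease", depth = 8,
                               duration_fwhm = 600, responder_fraction = 1))
  rec <- generate_yc_recording(eff, onsets = 400, n_rois = 4,
                               frame_interval = 1, session_duration = 2000,
                               noise_sd = 0.005, amplitude_jitter = 0,
                               seed = 11)
  ratio <- compute_yc_ratio(rec)
  zt <- correct_and_zscore(ratio, baseline_window = c(100, 400),
                           frame_interval = 1)
  # smoothed minimum of the noisy Z trace lands within 1 Z of -depth
  zmin <- vapply(seq_len(4), function(j)
    fwhm(zt$z[, j], onset = 400, frame_interval = 1)$z_min120, 0)
  expect_true(all(abs(zmin + 8) < 1))
  # FWHM on the noiseless kernel path (the generator's pre-noise truth)
  fw0 <- fwhm(rec$truth$z_expected[, 1], onset = 400, frame_interval = 1)
  expect_lt(abs(fw0$fwhm_seconds - 600) / 600, 0.10)
})

test_that("YC generator rejects overlapping applications and bad layouts", {
  eff <- list(substance_effect("A"), substance_effect("B"))
  expect_error(generate_yc_recording(eff, onsets = c(400, 450), n_rois = 2,
                                     frame_interval = 1),
               "overlapping")
  expect_error(generate_yc_recording(list(substance_effect("A")),
                                     onsets = 400, n_rois = 2,
                                     frame_interval = 1,
                                     session_duration = 450),
               "fit inside")
})

test_that("TST generator: ground-truth mask arithmetic and edge cases", {
  # bouts totaling 160 s of a 360 s session -> 200 s immobile truth
  bouts <- list(c(20, 80), c(120, 170), c(250, 300))
  sim <- generate_tst_area_series(duration = 360, frame_rate = 30,
                                  struggle_bouts = bouts, seed = 1)
  expect_equal(sum(!sim$truth$immobile) / 30, 160)
  expect_equal(sum(sim$truth$immobile) / 30, 200)

  none <- generate_tst_area_series(struggle_bouts = list(), seed = 1)
  expect_true(all(none$truth$immobile))
  full <- generate_tst_area_series(struggle_bouts = list(c(0, 360)), seed = 1)
  expect_false(any(full$truth$immobile))

  expect_error(generate_tst_area_series(pendulum_freq = 20, frame_rate = 30),
               "Nyquist")
  expect_error(generate_tst_area_series(struggle_bouts = list(c(300, 400))),
               "outside")
  s1 <- generate_tst_area_series(struggle_bouts = bouts, seed = 9)
  s2 <- generate_tst_area_series(struggle_bouts = bouts, seed = 9)
  expect_identical(s1$area, s2$area)
})

test_that("EEG/EMG generator encodes state-dependent features", {
  allw <- generate_eeg_emg(rep("W", 30), sample_rate = 100, seed = 5)
  allnr <- generate_eeg_emg(rep("NR", 30), sample_rate = 100, seed = 5)
  fw <- epoch_features(allw)
  fnr <- epoch_features(allnr)
  # W carries elevated EMG; NR carries delta above theta
  expect_gt(mean(fw$emg_rms), mean(fnr$emg_rms))
  expect_true(all(fnr$delta_amp > fnr$theta_amp))
  expect_gt(mean(fw$ir_activity), mean(fnr$ir_activity))
  expect_error(generate_eeg_emg(c("W", "Q")), "unknown state")
})

test_that("photometry generator: constants, artifact-only, and round trip", {
  sim <- generate_photometry_raw(rep(2, 60), settle_amp = 0, noise_sd = 0,
                                 seed = 1)
  de <- deinterleave(sim$raw)
  expect_equal(de$f470, sim$truth$f470)
  expect_equal(de$f405, sim$truth$f405)
  expect_lt(diff(range(de$f470)), 1e-12)

  art <- sin(seq(0, 8 * pi, length.out = 120))
  sim2 <- generate_photometry_raw(rep(0, 120), artifact = art,
                                  settle_amp = 0, noise_sd = 0)
  de2 <- deinterleave(sim2$raw)
  expect_lt(max(abs(isosbestic_correct(de2$f470, de2$f405))), 1e-9)

  # step latent, zero mean over first third: F_GC recovers the step
  lat <- c(rep(0, 200), rep(1, 100), rep(0, 100))
  sim3 <- generate_photometry_raw(lat, artifact = 0.3 * sin(1:400 / 10),
                                  seed = 3)
  de3 <- deinterleave(sim3$raw)
  fgc <- isosbestic_correct(de3$f470, de3$f405)
  step_hat <- mean(fgc[220:280]) - mean(fgc[50:150])
  expect_lt(abs(step_hat - sim3$truth$f_gc_expected[250]) /
              abs(sim3$truth$f_gc_expected[250]), 0.05)
})

test_that("clustered-values generator matches its variance contract", {
  one <- generate_clustered_values(4, 5, icc_true = 1, seed = 2)
  expect_true(all(tapply(one$values, one$cluster,
                         function(v) diff(range(v))) < 1e-12))
  zero <- generate_clustered_values(40, 25, icc_true = 0, seed = 3)
  expect_lt(abs(icc_oneway(zero$values, zero$cluster)$icc), 0.05)
  expect_error(generate_clustered_values(4, 5, icc_true = 1.5), "\\[0, 1\\]")
})
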