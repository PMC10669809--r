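test_that("Y/C ratio identities and CFP guard", {
  y <- runif(100, 500, 1500)
  expect_equal(compute_yc_ratio(list(yfp = y, cfp = y)), rep(1, 100))
  expect_equal(compute_yc_ratio(list(yfp = 2 * y, cfp = y)), rep(2, 100))
  expect_equal(compute_yc_ratio(list(yfp = 1.1, cfp = 0.9)), 1.1 / 0.9)
  cfp <- matrix(1, 10, 2, dimnames = list(NULL, c("roiA", "roiB")))
  cfp[4, 2] <- 0
  expect_error(compute_yc_ratio(list(yfp = cfp + 1, cfp = cfp)),
               "roiB, frame 4")
})

test_that("Z-scoring removes drift and normalizes the baseline", {
  # adding an exactly linear drift leaves the Z trace unchanged
  set.seed(4)
  r <- 1 + rnorm(1000, 0, 0.01)
  t <- 0:999
  zt_drift <- correct_and_zscore(r + 0.0005 * t, baseline_window = c(0, 300),
                                 frame_interval = 1)
  zt2 <- correct_and_zscore(r, baseline_window = c(0, 300),
                            frame_interval = 1)
  expect_equal(zt_drift$z, zt2$z, tolerance = 1e-9)

  base <- 1:300
  expect_lt(abs(mean(zt2$z[base])), 1e-6)
  expect_lt(abs(sd(zt2$z[base]) - 1), 1e-6)
})

test_that("Z-scoring recovers an injected dip and is affine-invariant", {
  set.seed(5)
  noise <- rnorm(1200, 0, 0.01)
  noise[450:750] <- 0  # keep the dip itself noiseless (hand-computable)
  base_sd <- sd(noise[1:300] - predict(lm(noise[1:300] ~ I(1:300))))
  dip <- numeric(1200)
  dip[500:700] <- -5 * base_sd * sin(seq(0, pi, length.out = 201))
  r <- 1 + noise + dip
  zt <- correct_and_zscore(r, c(0, 300), frame_interval = 1)
  expect_lt(abs(min(zt$z) + 5), 0.35)

  # gain/offset invariance of the Z trace
  zt2 <- correct_and_zscore(3.7 * r + 11, c(0, 300), frame_interval = 1)
  expect_equal(zt$z, zt2$z, tolerance = 1e-9)

  expect_error(correct_and_zscore(rep(1, 500), c(0, 300), 1), "SD is zero")
  expect_error(correct_and_zscore(r, c(0, 20), 1), ">= 30")
})

test_that("windowed mean response: constants, ramp, bounds", {
  z <- rep(3, 700)
  expect_equal(mean_response(z, onset = 100, frame_interval = 1), 3)
  expect_equal(mean_response(rep(0, 700), 100, frame_interval = 1), 0)
  z2 <- numeric(700)
  z2[101:400] <- seq(0, -6, length.out = 300)
  expect_equal(mean_response(z2, 100, frame_interval = 1), -3)
  expect_error(mean_response(z, onset = 500, frame_interval = 1),
               "past the recording end")
  # 10-11 min window preset
  z3 <- numeric(1000); z3[701:760] <- -4
  expect_equal(mean_response(z3, 100, response_window("receptor_id"),
                             frame_interval = 1), -4)
})

test_that("quartile classification rule and its guards", {
  up <- classify_substance(c(1.0, 2.5, 3.0, 4.0))
  expect_equal(up$classification, "increase")
  expect_equal(unname(up$quartiles["q3"]), 3.25)
  expect_equal(unname(up$quartiles["q3"]), naive_quantile(c(1, 2.5, 3, 4), 0.75))

  dn <- classify_substance(c(-5, -3, -2.5, -1))
  expect_equal(dn$classification, "decrease")
  expect_equal(unname(dn$quartiles["q1"]), -3.5)
  expect_equal(unname(dn$quartiles["q1"]),
               naive_quantile(c(-5, -3, -2.5, -1), 0.25))

  expect_equal(classify_substance(rep(0, 10))$classification, "none")
  expect_error(classify_substance(c(1, 2, 3)), ">= 4")
  expect_error(classify_substance(c(-8, -7, 7, 8)), "bimodal")
})

test_that("FWHM: worked example, exclusion, and oracle agreement", {
  z <- rep(0, 3000); z[1001:1501] <- -8
  fw <- fwhm(z, onset = 900, frame_interval = 1)
  expect_equal(fw$z_min120, -8)
  expect_equal(fw$t_from, 1001L)
  expect_equal(fw$t_to, 1501L)
  expect_equal(fw$fwhm_frames, 500L)
  expect_false(fw$censored)

  expect_true(fwhm(rep(0, 500), onset = 100, frame_interval = 1)$excluded)

  set.seed(6)
  for (i in 1:25) {
    n <- sample(500:900, 1)
    zr <- rnorm(n, 0, 0.5)
    w <- sample(60:300, 1)
    s <- sample(seq_len(n - w - 1), 1)
    zr[s:(s + w)] <- zr[s:(s + w)] - runif(1, 4, 10)
    onset <- max(0, min(s - 21, n - 300))
    got <- fwhm(zr, onset = onset, frame_interval = 1)
    ref <- naive_fwhm(zr, onset = onset)
    expect_equal(got$excluded, ref$excluded)
    if (!ref$excluded) {
      expect_equal(got$z_min120, ref$z_min120)
      expect_equal(got$t_from, ref$t_from)
      expect_equal(got$t_to, ref$t_to)
    }
  }
})

test_that("FWHM grows monotonically with the generated dip width", {
  durations <- c(100, 160, 220, 300, 400)
  measured <- vapply(durations, function(d) {
    t <- 0:1999
    z <- -8 * response_kernel(t, onset = 300, duration_fwhm = d)
    fwhm(z, onset = 300, frame_interval = 1)$fwhm_seconds
  }, 0)
  expect_true(all(diff(measured) > 0))
  expect_true(all(abs(measured - durations) <= 62))
})

test_that("peak dR/R0: flat, arithmetic, scale invariance", {
  flat <- rep(1, 200)
  expect_equal(peak_dr_over_r0(flat, c(60, 90), frame_interval = 1), 0)
  r <- rep(1, 200); r[71] <- 1.2
  expect_equal(peak_dr_over_r0(r, c(60, 90), frame_interval = 1), 0.2)
  expect_equal(peak_dr_over_r0(5 * r, c(60, 90), frame_interval = 1), 0.2)
  expect_error(peak_dr_over_r0(r, c(10, 40), frame_interval = 1),
               "pre-stimulus")
})

test_that("screen_session recovers control directions and flags bad baselines", {
  eff <- list(
    substance_effect("aCSF", "none"),
    substance_effect("Glu", "increase", depth = 6, duration_fwhm = 300,
                     responder_fraction = 0.9),
    substance_effect("GABA", "decrease", depth = 6, duration_fwhm = 300,
                     responder_fraction = 0.9))
  rec <- generate_yc_recording(eff, onsets = c(400, 1400, 2400),
                               n_rois = 24, frame_interval = 1, seed = 8)
  ss <- screen_session(rec)
  cl <- ss$classification
  expect_equal(cl$classification[match(c("aCSF", "Glu", "GABA"),
                                       cl$substance)],
               c("none", "increase", "decrease"))

  # second application 200 s after the first: baseline overlaps -> flagged
  eff2 <- list(substance_effect("A"), substance_effect("B"))
  rec2 <- generate_yc_recording(eff2, onsets = c(400, 600), n_rois = 4,
                                frame_interval = 1, seed = 9)
  ss2 <- screen_session(rec2)
  flagged <- ss2$roi_means[ss2$roi_means$substance == "B", ]
  expect_true(all(flagged$flagged))
  expect_true(all(is.na(flagged$mean_z)))
})
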