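test_that("deinterleaving: constants, ramp mean, channel symmetry, guards", {
  v <- rep(c(rep(1, 25), rep(2, 25)), 4)
  de <- deinterleave(raw_pmt_stream(v))
  expect_equal(de$f470, rep(1, 4))
  expect_equal(de$f405, rep(2, 4))

  ramp <- c(1:25, rep(0, 25))
  expect_equal(deinterleave(raw_pmt_stream(ramp))$f470, mean(13:24))
  expect_equal(deinterleave(raw_pmt_stream(ramp))$f470, 18.5)

  sw <- deinterleave(raw_pmt_stream(ramp, first_channel = "405"))
  expect_equal(sw$f405, 18.5)
  expect_equal(sw$f470, 0)

  expect_error(raw_pmt_stream(rep(0, 60)), "multiple")
})

test_that("isosbestic correction cancels proportional channels", {
  set.seed(18)
  x <- rnorm(90, 5, 1)
  expect_equal(isosbestic_correct(x, x), rep(0, 90))
  expect_equal(isosbestic_correct(2 * x, x), rep(0, 90))

  f470 <- c(1, 1, 1, 2, 2, 2, 1, 1, 1)
  fgc <- isosbestic_correct(f470, rep(1, 9))
  expect_equal(fgc, c(0, 0, 0, 1, 1, 1, 0, 0, 0))

  expect_error(isosbestic_correct(1:2, 1:2), "first third")
  expect_error(isosbestic_correct(rep(1, 9), rep(0, 9)), "zero")
})

test_that("smoothing and min-max normalization", {
  ramp <- seq(0, 1, length.out = 100)
  s <- smooth_and_normalize(ramp)
  expect_equal(min(s$f_tsre), 0)
  expect_equal(max(s$f_tsre), 1)
  # a linear ramp stays linear after boxcar smoothing (interior)
  expect_lt(max(abs(diff(diff(s$f_tsre[15:95])))), 1e-12)

  set.seed(19)
  x <- seq(0, 2, length.out = 200) + rnorm(200, 0, 0.1)
  s2 <- smooth_and_normalize(x)
  expect_equal(s2$f_ts, naive_trailing_ma(x, 10))
  expect_equal(range(s2$f_tsre), c(0, 1))

  expect_error(smooth_and_normalize(rep(1, 50)), "constant")
  expect_error(smooth_and_normalize(1:5), "fewer than")
})

test_that("epoch normalization anchors, onset value, validity flags", {
  f <- c(0.3, 0.8, 0.6, 0.5, 0.2, 0.1, 0.15)
  ep <- data.frame(mobile_start = 1, mobile_end = 3,
                   immobile_start = 4, immobile_end = 7)
  out <- epoch_normalize(f, ep)
  expect_equal(out$epochs$f_eonset, (0.5 - 0.1) / (0.8 - 0.1))
  expect_equal(out$epochs$f_eonset, 4 / 7)
  # anchor samples: mobile max -> 1, immobile min -> 0
  expect_equal(max(out$f_enorm[[1]][1:3]), 1)
  expect_equal(min(out$f_enorm[[1]][4:7]), 0)

  # onset at the immobile minimum -> 0
  f2 <- c(0.2, 0.9, 0.5, 0.1, 0.3, 0.4)
  ep2 <- data.frame(mobile_start = 1, mobile_end = 3,
                    immobile_start = 4, immobile_end = 6)
  expect_equal(epoch_normalize(f2, ep2)$epochs$f_eonset, 0)

  # onset at the mobile max with immobile min below -> bounded by 1
  f3 <- c(0.1, 0.5, 0.9, 0.9, 0.2, 0.3)
  expect_lte(epoch_normalize(f3, ep2)$epochs$f_eonset, 1)

  # invalid epoch (max <= min) flagged, excluded from the mean
  f4 <- c(0.1, 0.1, 0.1, 0.5, 0.6, 0.7, 0.3, 0.9, 0.2, 0.05, 0.02, 0.01)
  ep4 <- data.frame(mobile_start = c(1, 7), mobile_end = c(3, 9),
                    immobile_start = c(4, 10), immobile_end = c(6, 12))
  out4 <- epoch_normalize(f4, ep4)
  expect_false(out4$epochs$valid[1])
  expect_true(out4$epochs$valid[2])
  expect_equal(out4$mean_f_eonset, out4$epochs$f_eonset[2])
  expect_error(epoch_normalize(f4[1:6], ep4[1, ]), "no valid epochs")
})

test_that("full chain recovers a latent transient from the raw stream", {
  n <- 600
  lat <- numeric(n)
  lat[250:420] <- sin(seq(0, pi, length.out = 171))
  art <- 0.4 * sin((1:n) / 15)
  sim <- generate_photometry_raw(lat, art, seed = 20)
  de <- deinterleave(sim$raw)
  fgc <- isosbestic_correct(de$f470, de$f405)
  # correlation with expected corrected signal, artifact rejected
  expect_gt(abs(cor(fgc, sim$truth$f_gc_expected)), 0.98)
  resid <- fgc - sim$truth$f_gc_expected
  expect_lt(abs(cor(resid[50:n], art[50:n])), 0.3)
})

test_that("earlier calcium decay yields lower mean onset values", {
  # latent decays before vs after immobility onset; same epochs
  n <- 400
  epochs <- data.frame(mobile_start = c(41, 241), mobile_end = c(120, 320),
                       immobile_start = c(121, 321),
                       immobile_end = c(200, 400))
  make_latent <- function(lag) {
    lat <- numeric(n)
    for (i in seq_len(nrow(epochs))) {
      on <- epochs$immobile_start[i] + lag
      up <- epochs$mobile_start[i]:min(on - 1, n)
      lat[up] <- 1
      dn <- on:min(on + 39, n)
      lat[dn] <- seq(1, 0, length.out = length(dn))
    }
    lat
  }
  run <- function(lag, seed) {
    sim <- generate_photometry_raw(make_latent(lag), seed = seed)
    de <- deinterleave(sim$raw)
    s <- smooth_and_normalize(isosbestic_correct(de$f470, de$f405))
    # PMT voltages are negative-going; invert for the behavioral contrast
    epoch_normalize(1 - s$f_tsre, epochs)$mean_f_eonset
  }
  early <- run(-30, 21)
  late <- run(+20, 21)
  expect_lt(early, late)
})
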