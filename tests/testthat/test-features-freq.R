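test_that("zero-padded spectrum has the stated length and peak bin", {
  sp <- zero_padded_spectrum(stats::rnorm(100), 256L)
  expect_length(sp, 129L)
  expect_false(attr(sp, "truncated"))
  ## 250 Hz tone at 2500 Hz, 256-point DFT: bin 250 / (2500/256) = 25.6
  x <- sin(2 * pi * 250 * (0:255) / 2500)
  sp2 <- zero_padded_spectrum(x, 256L)
  peak_bin <- which.max(sp2[-1])          # bins count from DC
  expect_lte(abs(peak_bin - 250 / (2500 / 256)), 1)
  expect_true(all(zero_padded_spectrum(rep(0, 50), 256L) == 0))
  ## longer segments truncate, flagged
  sp3 <- zero_padded_spectrum(stats::rnorm(500), 256L)
  expect_true(attr(sp3, "truncated"))
})

test_that("spectral summary matches its definitional loop", {
  ## flat power over n bins has entropy log2(n)
  flat <- spectral_summary(rep(1, 128), 2500)
  expect_equal(flat$entropy, 7)
  ## a single non-zero bin: zero entropy, center and peak at its frequency
  spec <- rep(0, 129); n_fft <- 256
  bin_hz <- 2500 / n_fft
  i300 <- round(300 / bin_hz) + 1L
  spec[i300] <- 4
  one <- spectral_summary(spec, 2500)
  expect_equal(one$entropy, 0)
  expect_equal(one$center, (i300 - 1) * bin_hz)
  expect_equal(one$peak_freq, (i300 - 1) * bin_hz)
  ## random spectrum vs brute-force definitional loop
  set.seed(7)
  sp <- stats::runif(129)
  res <- spectral_summary(sp, 2500)
  p <- sp^2 / sum(sp^2)
  ent <- 0; cen <- 0
  for (i in seq_along(p)) {
    f <- (i - 1) * bin_hz
    if (p[i] > 0) ent <- ent - p[i] * log2(p[i])
    cen <- cen + f * p[i]
  }
  expect_equal(res$entropy, ent, tolerance = 1e-9)
  expect_equal(res$center, cen, tolerance = 1e-9)
  ## all-zero spectrum: zeros, flagged
  z <- spectral_summary(rep(0, 10), 2500)
  expect_true(z$flagged)
  expect_equal(c(z$entropy, z$center, z$peak_freq), c(0, 0, 0))
})

test_that("fundamental statistics recover known pitches", {
  rate <- 2500
  t <- seq(0, 1, by = 1 / rate)
  saw <- 2 * ((50 * t) %% 1) - 1
  f0 <- fundamental_stats(saw, rate)
  expect_false(f0$flagged)
  expect_equal(f0$mean_f0, 50, tolerance = 2)
  expect_lt(f0$max_f0 - f0$min_f0, 5)
  ## concatenated 40 Hz then 80 Hz sawtooth: min near 40, max near 80
  saw40 <- 2 * ((40 * t) %% 1) - 1
  saw80 <- 2 * ((80 * t) %% 1) - 1
  f2 <- fundamental_stats(c(saw40, saw80), rate)
  expect_equal(f2$min_f0, 40, tolerance = 3)
  expect_equal(f2$max_f0, 80, tolerance = 3)
  expect_true(f2$min_f0 <= f2$mean_f0 && f2$mean_f0 <= f2$max_f0)
})

test_that("dominant frequencies find and deduplicate per-frame PSD peaks", {
  rate <- 2500
  t <- seq(0, 1, by = 1 / rate)
  x <- sin(2 * pi * 60 * t) + sin(2 * pi * 200 * t)
  d <- dominant_frequencies(x, rate)
  expect_false(d$flagged)
  expect_true(any(abs(d$frequencies - 60) <= 20))
  expect_true(any(abs(d$frequencies - 200) <= 20))
  expect_equal(d$range_d, 140, tolerance = 25)
  ## single tone: range 0
  d1 <- dominant_frequencies(sin(2 * pi * 100 * t), rate)
  expect_equal(d1$range_d, 0)
  ## amplitude scaling leaves the set unchanged
  d2 <- dominant_frequencies(7 * x, rate)
  expect_equal(d$frequencies, d2$frequencies)
})

test_that("the assembled frequency vector respects its invariants", {
  g <- generate_record(synthetic_spec("CHD", seed = 3))
  rec <- preprocess_record(g$record)
  cyc <- extract_cycles(rec, g$truth)[[2]]
  ff <- freq_features(cyc$cycle, cyc$s2, 2500)
  expect_true(all(is.finite(ff)))
  expect_true(all(ff[grepl("^(c|pf|af|minf|maxf|ad|mind|maxd|dd)_", names(ff))] <= 1250))
  expect_lte(ff[["minf_cc"]], ff[["af_cc"]])
  expect_lte(ff[["af_cc"]], ff[["maxf_cc"]])
  expect_lte(ff[["mind_s2"]], ff[["ad_s2"]])
  expect_lte(ff[["ad_s2"]], ff[["maxd_s2"]])
  expect_equal(ff[["dd_cc"]], ff[["maxd_cc"]] - ff[["mind_cc"]])
  ## optional higher-order moments only appear on request
  expect_false(any(grepl("skew|kurt", names(ff))))
  ff2 <- freq_features(cyc$cycle, cyc$s2, 2500, higher_order = TRUE)
  expect_true(all(c("skew_cc", "kurt_s2") %in% names(ff2)))
})
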