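test_that("pre-emphasis applies y[n] = x[n] - 0.95 x[n-1]", {
  expect_equal(pre_emphasis(c(1, 1, 1)), c(1, 0.05, 0.05))
  expect_equal(pre_emphasis(c(1, 0, 0)), c(1, -0.95, 0))
  ## high-pass behaviour: a DC-heavy signal loses most of its mean level
  x <- 1 + 0.01 * sin(2 * pi * 200 * (0:999) / 2500)
  y <- pre_emphasis(x)
  expect_lt(mean(abs(y[-1])), 0.1 * mean(abs(x)))
})

test_that("adaptive STFT yields a fixed frame count for any cycle length", {
  for (n in c(1500L, 2400L, 700L)) {
    st <- adaptive_stft(stats::rnorm(n), n_frames_out = 64L)
    expect_equal(ncol(st$spectra), 64L)
  }
  ## single output frame covers the whole cycle
  x <- stats::rnorm(300)
  st1 <- adaptive_stft(x, n_frames_out = 1L)
  expect_equal(ncol(st1$spectra), 1L)
  expect_equal(st1$frame_len, 300L)
  expect_error(adaptive_stft(stats::rnorm(32), 64L), "shorter")
  ## a constant-frequency input peaks at the same Hz in every frame
  tone <- sin(2 * pi * 200 * (0:1999) / 2500)
  st <- adaptive_stft(tone, 16L)
  peaks <- apply(Mod(st$spectra), 2L, which.max)
  peak_hz <- st$freqs[peaks]
  bin <- st$freqs[2] - st$freqs[1]
  expect_true(all(abs(peak_hz - 200) <= bin + 1e-9))
})

test_that("the gammatone filterbank is unit-normalized per channel", {
  freqs <- (0:128) * 2500 / 256
  fb <- gammatone_fbank(freqs, 40L)
  expect_equal(dim(fb), c(129L, 40L))
  expect_true(all(abs(colSums(fb) - 1) < 1e-6))
  ## white spectrum -> unit power in every channel
  spectra <- matrix(1 + 0i, 129, 5)
  P <- filterbank_power(spectra, fb)
  expect_true(all(abs(P - 1) < 1e-9))
  expect_true(all(filterbank_power(matrix(0i, 129, 3), fb) == 0))
})

test_that("a narrowband tone lands in the matching filterbank channel", {
  x <- sin(2 * pi * 150 * (0:1999) / 2500)
  st <- adaptive_stft(x, 16L)
  fb <- gammatone_fbank(st$freqs, 40L)
  P <- filterbank_power(st$spectra, fb)
  erb <- function(f) 21.4 * log10(1 + 0.00437 * f)
  centers <- (10^(seq(erb(25), erb(1000), length.out = 40) / 21.4) - 1) / 0.00437
  expect_lte(abs(which.max(colMeans(P)) - which.min(abs(centers - 150))), 1L)
})

test_that("medium-time power is the shrinking-window running mean", {
  ## constant input is a fixed point
  P <- matrix(3, 10, 4)
  expect_equal(medium_time_power(P, 2L), P)
  ## an interior impulse spreads over 2M + 1 frames at 1/5 height
  P2 <- matrix(0, 11, 1); P2[6, 1] <- 1
  Q2 <- medium_time_power(P2, 2L)
  expect_equal(Q2[4:8, 1], rep(0.2, 5))
  expect_equal(sum(Q2[c(1:3, 9:11), 1]), 0)
  ## random input matches a brute-force loop
  set.seed(8)
  P3 <- matrix(stats::runif(60), 12, 5)
  Q3 <- medium_time_power(P3, 2L)
  for (m in 1:12) for (l in 1:5) {
    win <- max(1, m - 2):min(12, m + 2)
    expect_equal(Q3[m, l], mean(P3[win, l]), tolerance = 1e-12)
  }
})

test_that("asymmetric noise suppression keeps bursts and kills pedestals", {
  cfg <- pncc_config()
  ## zero in, zero out
  expect_true(all(asymmetric_noise_suppression(matrix(0, 20, 4), cfg) == 0))
  ## constant input converges to a small residual below the input
  Qc <- matrix(2, 300, 2)
  Rc <- asymmetric_noise_suppression(Qc, cfg)
  expect_true(all(Rc <= 2 + 1e-12))
  expect_lt(mean(Rc[250:300, ]), 0.5)
  ## burst on a pedestal: burst preserved, steady-state pedestal cut >= 10 dB
  Qb <- matrix(1, 400, 1)
  Qb[201:205, 1] <- 50
  Rb <- asymmetric_noise_suppression(Qb, cfg)
  expect_gt(max(Rb[201:205, 1]), 10)                     # burst survives
  expect_lt(mean(Rb[150:199, 1]), 1 / 10)                # >= 10 dB down
  expect_true(all(Rb >= 0))
})

test_that("spectral weight smoothing matches its double loop", {
  set.seed(9)
  n <- 12L; L <- 10L; N <- 4L
  Q <- matrix(stats::runif(n * L, 0.5, 2), n, L)
  R <- matrix(stats::runif(n * L, 0, 2), n, L)
  P <- matrix(stats::runif(n * L, 0, 3), n, L)
  T1 <- spectral_weight_smoothing(R, Q, P, N)
  for (m in 1:n) for (l in 1:L) {
    l1 <- max(l - N, 1); l2 <- min(l + N, L)
    s <- mean(R[m, l1:l2] / Q[m, l1:l2])
    expect_equal(T1[m, l], P[m, l] * s, tolerance = 1e-12)
  }
  ## identity transfer and annihilation
  expect_equal(spectral_weight_smoothing(Q, Q, P, N), P, tolerance = 1e-12)
  expect_true(all(spectral_weight_smoothing(0 * Q, Q, P, N) == 0))
})

test_that("power normalization reaches the closed-form steady state", {
  cfg <- pncc_config()
  ## constant T = c: mu = c from the first frame, U = k = 1, V = 1
  Tm <- matrix(5, 30, 8)
  V <- power_normalize(Tm, cfg)
  expect_true(all(abs(V - 1) < 1e-12))
  ## arbitrary k: V = k^(1/15)
  cfg2 <- pncc_config(scale_k = 3)
  V2 <- power_normalize(Tm, cfg2)
  expect_true(all(abs(V2 - 3^(1 / 15)) < 1e-12))
  ## zero input is guarded, flagged, and returns zeros
  V0 <- power_normalize(matrix(0, 5, 4), cfg)
  expect_true(all(V0 == 0))
  expect_true(attr(V0, "flagged"))
})

test_that("the PNCC image is amplitude invariant with a fixed shape", {
  g <- generate_record(synthetic_spec("CHD-PAH", seed = 14))
  rec <- preprocess_record(g$record)
  cycs <- extract_cycles(rec, g$truth)
  for (cw in cycs[2:4]) {
    im <- pncc_image(cw$cycle)
    expect_equal(dim(im), c(64L, 40L))
    expect_true(all(is.finite(im)) && all(im >= 0))
    for (c_scale in c(0.1, 10)) {
      im2 <- pncc_image(c_scale * cw$cycle)
      expect_lt(max(abs(im2 - im)), 1e-6)
    }
  }
})
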