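## Brute-force per-frame envelope oracle, kept deliberately loop-based and
## independent of the vectorized implementation.
envelope_oracle <- function(x, frame_len, rate) {
  n_frames <- length(x) %/% frame_len
  E <- S <- numeric(n_frames)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(frame_len - 1)) / (frame_len - 1))
  for (i in seq_len(n_frames)) {
    fr <- x[((i - 1) * frame_len + 1):(i * frame_len)]
    acc <- 0
    for (v in fr) acc <- acc + abs(v)^2
    E[i] <- acc / frame_len
    sp <- Mod(stats::fft(fr * w))[1:(frame_len %/% 2 + 1)]^2
    fq <- (0:(frame_len %/% 2)) * rate / frame_len
    tot <- sum(sp)
    if (tot > 0) {
      mu <- sum(fq * sp) / tot
      S[i] <- sqrt(sum((fq - mu)^2 * sp) / tot)
    }
  }
  list(E = E, S = S)
}

test_that("energy and spread envelopes match a brute-force oracle", {
  set.seed(10)
  rec <- pcg_record(stats::rnorm(2500), 2500)
  env <- compute_envelopes(rec, window_s = 0.1)
  orc <- envelope_oracle(rec$samples, env$frame_len, 2500)
  expect_equal(env$energies, orc$E, tolerance = 1e-9)
  expect_equal(env$spreads, orc$S, tolerance = 1e-9)
  expect_true(all(env$spreads >= 0 & env$spreads <= 1250))
})

test_that("envelope degenerate cases follow the stated conventions", {
  ## alternating +/-1 frame has unit mean-square energy
  rec <- pcg_record(rep(c(1, -1), 500), 2500)
  env <- compute_envelopes(rec, window_s = 4 / 2500)
  expect_true(all(abs(env$energies - 1) < 1e-12))
  ## all-zero record: energy 0, spread 0 by convention
  env0 <- compute_envelopes(pcg_record(rep(0, 500), 2500), window_s = 0.1)
  expect_true(all(env0$energies == 0))
  expect_true(all(env0$spreads == 0))
  ## a pure sinusoid frame concentrates its spectrum: spread within leakage
  env1 <- compute_envelopes(tone_record(100, dur_s = 0.1), window_s = 0.1)
  expect_lt(env1$spreads[1], 30)
  expect_error(compute_envelopes(pcg_record(rep(0, 10), 2500), window_s = 0.1),
               "shorter")
})

test_that("adaptive threshold is the W-weighted mean of the two modes", {
  set.seed(3)
  ## dominant mode at 2, secondary at 5
  values <- c(stats::rnorm(700, 2, 0.05), stats::rnorm(300, 5, 0.05))
  t5 <- adaptive_threshold(values, W = 5)
  bw <- diff(range(values)) / 50
  expect_false(attr(t5, "fallback"))
  expect_lt(abs(attr(t5, "M1") - 2), 3 * bw)
  expect_lt(abs(attr(t5, "M2") - 5), 3 * bw)
  expect_equal(as.numeric(t5),
               (5 * attr(t5, "M1") + attr(t5, "M2")) / 6, tolerance = 1e-12)
  ## limits: W = 0 -> M2; W -> Inf -> M1
  t0 <- adaptive_threshold(values, W = 0)
  expect_equal(as.numeric(t0), attr(t0, "M2"), tolerance = 1e-12)
  tinf <- adaptive_threshold(values, W = 1e6)
  expect_lt(abs(as.numeric(tinf) - attr(tinf, "M1")), 1e-4)
})

test_that("bimodal thresholds fall strictly between the modes", {
  set.seed(4)
  for (i in 1:5) {
    values <- c(stats::runif(400, 0.05, 0.15), stats::runif(200, 0.9, 1.1))
    t <- adaptive_threshold(values, W = 5)
    expect_gt(as.numeric(t), 0.15)
    expect_lt(as.numeric(t), 0.9)
  }
})

test_that("threshold falls back on unimodal data, flagged", {
  set.seed(5)
  values <- stats::rnorm(1000)
  t <- adaptive_threshold(values)
  if (attr(t, "fallback"))
    expect_equal(as.numeric(t), mean(values) + 0.5 * stats::sd(values))
  const <- adaptive_threshold(rep(1, 10))
  expect_true(attr(const, "fallback"))
})

test_that("component merging follows the strict 50 ms rule and is idempotent", {
  rate <- 2500
  ## gap of 20 ms merges
  comp <- data.frame(start = c(0L, 150L), end = c(100L, 250L))
  m <- merge_components(comp, 50, rate)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(0L, 250L))
  ## gap of exactly 50 ms does not
  comp2 <- data.frame(start = c(0L, 225L), end = c(100L, 325L))
  expect_equal(nrow(merge_components(comp2, 50, rate)), 2L)
  ## idempotence + all post-merge gaps >= merge distance
  set.seed(6)
  starts <- sort(sample.int(50000, 40))
  comp3 <- data.frame(start = starts, end = starts + sample(50:300, 40, TRUE))
  comp3 <- comp3[c(TRUE, diff(starts) > 400), ]
  m1 <- merge_components(comp3, 50, rate)
  m2 <- merge_components(m1, 50, rate)
  expect_identical(m1, m2)
  if (nrow(m1) > 1L)
    expect_true(all((m1$start[-1] - m1$end[-nrow(m1)]) / rate >= 0.05))
})

test_that("every clean synthetic burst is covered by a detected component", {
  g <- generate_record(synthetic_spec("Normal", heart_rate_bpm = 75,
                                      noise_snr_db = 25, seed = 21))
  rec <- preprocess_record(g$record)
  env <- compute_envelopes(rec)
  tE <- adaptive_threshold(env$energies)
  tS <- adaptive_threshold(env$spreads)
  comp <- detect_components(env, as.numeric(tE), as.numeric(tS),
                            samples = rec$samples)
  tru <- g$truth[g$truth$label %in% c("s1", "s2"), ]
  overlap <- vapply(seq_len(nrow(tru)), function(i) {
    any(pmin(comp$end, tru$end[i]) - pmax(comp$start, tru$start[i]) > 0)
  }, logical(1))
  expect_gte(mean(overlap), 0.95)
  ## close to one component per burst
  expect_lt(abs(nrow(comp) - nrow(tru)), 0.1 * nrow(tru) + 2)
})

test_that("no passing frame yields an empty component list", {
  env <- compute_envelopes(pcg_record(rep(0.001, 1000), 2500), 0.1)
  comp <- detect_components(env, t_energy = 1, t_spread = 0,
                            spread_direction = "<=", refine = FALSE)
  expect_equal(nrow(comp), 0L)
})

test_that("the maximal gap anchors S2 -> S1 and labels alternate", {
  ## components with gaps 0.20, 0.45, 0.21, 0.44 s (in samples at 2500 Hz)
  durs <- rep(250L, 6)
  gaps <- as.integer(c(0.20, 0.45, 0.21, 0.44, 0.20) * 2500)
  starts <- cumsum(c(1000L, head(durs, -1) + gaps))
  comp <- data.frame(start = starts, end = starts + durs)
  ann <- label_components(comp, max(comp$end) + 1000L, 2500)
  expect_false(isTRUE(attr(ann, "unsegmentable")))
  ## first component after the 0.45 gap is S1; its predecessor is S2
  s1 <- ann[ann$label == "s1", ]
  expect_true(all(s1$start %in% comp$start[c(3, 5)]))
  ## within each cycle the four labels appear once, in order, contiguous
  for (cy in split(ann, ann$cycle)) {
    expect_identical(cy$label, c("s1", "systole", "s2", "diastole"))
    expect_true(all(cy$start[-1] == cy$end[-4]))
  }
})

test_that("a spurious extra component drops only its own cycle", {
  durs <- rep(250L, 9)
  gaps <- as.integer(rep(c(0.20, 0.45), length.out = 8) * 2500)
  starts <- cumsum(c(1000L, head(durs, -1) + gaps))
  comp <- data.frame(start = starts, end = starts + durs)
  clean <- label_components(comp, max(comp$end) + 2000L, 2500)
  n_clean <- max(clean$cycle)
  ## inject a short spurious component early in one diastole
  bad <- rbind(comp, data.frame(start = comp$end[4] + 125L,
                                end = comp$end[4] + 225L))
  bad <- bad[order(bad$start), ]
  ann <- label_components(bad, max(bad$end) + 2000L, 2500)
  expect_false(isTRUE(attr(ann, "unsegmentable")))
  expect_equal(max(ann$cycle), n_clean - 1L)
})

test_that("fewer than four components is unsegmentable", {
  comp <- data.frame(start = c(0L, 1000L, 2000L), end = c(100L, 1100L, 2100L))
  ann <- label_components(comp, 5000L, 2500)
  expect_true(attr(ann, "unsegmentable"))
  expect_equal(nrow(ann), 0L)
})

test_that("extract_cycles slices cycle and S2 waveforms exactly", {
  rec <- pcg_record(seq_len(5000) / 5000, 2500)
  ann <- data.frame(cycle = 1L,
                    label = c("s1", "systole", "s2", "diastole"),
                    start = c(1000L, 1400L, 2100L, 2350L),
                    end   = c(1400L, 2100L, 2350L, 3000L))
  cyc <- extract_cycles(rec, ann)
  expect_length(cyc, 1L)
  expect_length(cyc[[1]]$cycle, 2000L)
  expect_length(cyc[[1]]$s2, 250L)
  expect_equal(cyc[[1]]$offset, 1000L)
  expect_equal(cyc[[1]]$s2, rec$samples[2101:2350])
  ## unsegmentable record gives an empty list
  un <- label_components(data.frame(start = integer(0), end = integer(0)),
                         5000L, 2500)
  expect_length(extract_cycles(rec, un), 0L)
})

test_that("a 20 s record at 75 bpm yields 23-25 cycles end to end", {
  g <- generate_record(synthetic_spec("Normal", heart_rate_bpm = 75,
                                      cycle_jitter = 0, seed = 8))
  expect_equal(max(g$truth$cycle), 25L)
  rec <- preprocess_record(g$record)
  ann <- segment_record(rec)
  expect_gte(max(ann$cycle), 23L)
  expect_lte(max(ann$cycle), 25L)
})

test_that("emitted annotations alternate labels and stay within bounds", {
  g <- generate_record(synthetic_spec("CHD", heart_rate_bpm = 88, seed = 13))
  rec <- preprocess_record(g$record)
  ann <- segment_record(rec)
  expect_gt(nrow(ann), 0)
  comps <- ann[ann$label %in% c("s1", "s2"), ]
  per_cycle <- split(ann, ann$cycle)
  for (cy in per_cycle) {
    expect_identical(cy$label, c("s1", "systole", "s2", "diastole"))
    dur <- (max(cy$end) - min(cy$start)) / 2500
    expect_gte(dur, 0.4); expect_lte(dur, 1.5)
  }
})
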