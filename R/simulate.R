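## Synthetic phonocardiogram generator with exact ground-truth annotations.
##
## Each cardiac cycle is S1 burst -> systolic gap (with a band-limited
## murmur for the CHD classes) -> S2 burst -> diastolic gap.  Bursts are
## Gaussian-windowed downward chirps, morphologically closer to real heart
## sounds than pure tones.  The class morphology follows auscultation: a
## normal S2 is a single lobe; CHD adds a small split and a systolic murmur;
## CHD-PAH shows a hyperactive (louder) S2 with a wide A2-P2 split.  All
## spectral content lies below 1000 Hz, matching the premise that the
## working band of the heart sound contains everything relevant.

#' Synthetic record specification
#'
#' Defaults per class (`split_ms` = A2-P2 delay; `s2_gain` multiplies the S2
#' amplitude; `p2_rel_amp` is the P2/A2 amplitude ratio):
#' Normal — split 0 ms, gain 1.0, no murmur;
#' CHD — split 15 ms, gain 1.2, systolic murmur;
#' CHD-PAH — split 40 ms, gain 1.6, `p2_rel_amp` 0.8, systolic murmur.
#'
#' @param class_label One of [pah_classes()].
#' @param heart_rate_bpm Heart rate (default drawn in 60-100 by
#'   [generate_dataset()]; here a fixed default of 75).
#' @param record_s Record duration in seconds (default 20).
#' @param noise_snr_db Additive-noise SNR in dB (default 15).
#' @param cycle_jitter Per-cycle period jitter fraction (default 0.03).
#' @param seed RNG seed; the record is fully determined by the spec.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(class_label = "Normal", heart_rate_bpm = 75,
                           record_s = 20, noise_snr_db = 15,
                           cycle_jitter = 0.03, seed = 1L) {
  class_label <- match.arg(class_label, pah_classes())
  cls <- switch(class_label,
    "Normal"  = list(split_ms = 0,  s2_gain = 1.0, p2_rel_amp = 0,   murmur_level = 0),
    "CHD"     = list(split_ms = 15, s2_gain = 1.2, p2_rel_amp = 0.7, murmur_level = 0.04),
    "CHD-PAH" = list(split_ms = 40, s2_gain = 1.6, p2_rel_amp = 0.8, murmur_level = 0.04))
  structure(list(
    class_label = class_label, heart_rate_bpm = heart_rate_bpm,
    record_s = record_s, noise_snr_db = noise_snr_db,
    cycle_jitter = cycle_jitter, seed = as.integer(seed),
    s1 = list(center_freq = 50, duration_ms = 120, amplitude = 1.0),
    s2 = list(center_freq = 70, duration_ms = 100, amplitude = 0.8,
              split_ms = cls$split_ms, p2_rel_amp = cls$p2_rel_amp,
              gain = cls$s2_gain),
    murmur = list(band = c(120, 400), level = cls$murmur_level),
    systole_frac = 0.35   # S2 onset as a fraction of the cycle: diastole
                          # remains the longest inter-sound interval at any
                          # admissible heart rate
  ), class = "synthetic_spec")
}

## Gaussian-enveloped downward chirp; returns `n` samples.
heart_burst <- function(n, rate, f0, amp, chirp_frac = 0.15, phase = 0) {
  t <- (seq_len(n) - 1) / rate
  dur <- n / rate
  f_inst <- f0 * (1 - chirp_frac * t / dur)      # downward 10-20% chirp
  phi <- 2 * pi * cumsum(f_inst) / rate + phase
  env <- exp(-0.5 * ((t - dur / 2) / (dur / 5))^2)
  amp * env * sin(phi)
}

## Band-limited noise via FFT masking; deterministic under the active RNG.
bandlimited_noise <- function(n, rate, f_lo, f_hi) {
  x <- stats::rnorm(n)
  sp <- stats::fft(x)
  freqs <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * rate / n
  mask <- abs(freqs) >= f_lo & abs(freqs) <= f_hi
  sp[!mask] <- 0
  y <- Re(stats::fft(sp, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s > 0) y / s else y
}

#' Generate one synthetic record with ground truth
#'
#' @param spec A [synthetic_spec()].
#' @param rate Sample rate in Hz (default 2500).
#' @return `list(record, truth)`: a [pcg_record()] and a ground-truth
#'   `data.frame(cycle, label, start, end)` in 0-based half-open sample
#'   coordinates, the four intervals tiling each cycle exactly.
#' @export
generate_record <- function(spec, rate = 2500) {
  stopifnot(inherits(spec, "synthetic_spec"))
  s2d <- spec$s2
  if (s2d$split_ms / 1000 > s2d$duration_ms / 1000 + 0.05)
    stop("generate_record: infeasible spec: split longer than S2")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(spec$seed)

  n_total <- as.integer(round(spec$record_s * rate))
  x <- numeric(n_total)
  period0 <- 60 / spec$heart_rate_bpm
  s1_len <- as.integer(round(spec$s1$duration_ms / 1000 * rate))
  split <- s2d$split_ms / 1000
  s2_core <- s2d$duration_ms / 1000
  s2_len <- as.integer(round((s2_core + split) * rate))

  truth <- list()
  pos <- 0L
  ci <- 0L
  while (TRUE) {
    period <- period0 * (1 + spec$cycle_jitter * stats::rnorm(1))
    period <- max(period, (s1_len + s2_len) / rate / (1 - spec$systole_frac) + 0.15)
    sys_end_s <- spec$systole_frac * period
    n_cycle <- as.integer(round(period * rate))
    if (pos + n_cycle > n_total) break
    ci <- ci + 1L

    ## S1
    s1 <- heart_burst(s1_len, rate, spec$s1$center_freq, spec$s1$amplitude)
    x[(pos + 1L):(pos + s1_len)] <- x[(pos + 1L):(pos + s1_len)] + s1

    ## S2: A2 lobe, plus a delayed P2 lobe when split
    s2_start <- pos + as.integer(round(sys_end_s * rate))
    lobe_len <- as.integer(round(0.060 * rate))
    a2 <- heart_burst(lobe_len, rate, s2d$center_freq,
                      s2d$amplitude * s2d$gain)
    seg <- numeric(s2_len)
    seg[seq_len(lobe_len)] <- a2
    if (s2d$split_ms > 0) {
      off <- as.integer(round(split * rate))
      p2 <- heart_burst(lobe_len, rate, s2d$center_freq * 0.9,
                        s2d$amplitude * s2d$gain * s2d$p2_rel_amp)
      idx <- (off + 1L):min(s2_len, off + lobe_len)
      seg[idx] <- seg[idx] + p2[seq_along(idx)]
    }
    x[(s2_start + 1L):(s2_start + s2_len)] <-
      x[(s2_start + 1L):(s2_start + s2_len)] + seg

    ## systolic murmur for CHD classes
    if (spec$murmur$level > 0) {
      sys_a <- pos + s1_len
      sys_b <- s2_start
      if (sys_b > sys_a) {
        mur <- bandlimited_noise(sys_b - sys_a, rate,
                                 spec$murmur$band[1L], spec$murmur$band[2L])
        ramp <- sin(pi * seq_len(sys_b - sys_a) / (sys_b - sys_a))
        x[(sys_a + 1L):sys_b] <- x[(sys_a + 1L):sys_b] +
          spec$murmur$level * mur * ramp
      }
    }

    truth[[ci]] <- data.frame(
      cycle = ci,
      label = c("s1", "systole", "s2", "diastole"),
      start = c(pos, pos + s1_len, s2_start, s2_start + s2_len),
      end   = c(pos + s1_len, s2_start, s2_start + s2_len, pos + n_cycle))
    pos <- pos + n_cycle
  }
  truth <- do.call(rbind, truth)

  ## additive broadband noise, band-limited below 1000 Hz
  sig_pow <- mean(x[seq_len(max(pos, 1L))]^2)
  noise <- bandlimited_noise(n_total, rate, 1, 1000)
  noise_pow <- sig_pow / 10^(spec$noise_snr_db / 10)
  x <- x + sqrt(noise_pow) * noise

  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  rec <- pcg_record(x, rate,
                    record_id = sprintf("sim_%s_%d", spec$class_label, spec$seed),
                    label = spec$class_label)
  list(record = rec, truth = truth)
}

#' Generate a balanced labelled corpus
#'
#' `n_per_class` records per class with per-record jitter of heart rate and
#' SNR, fully determined by `seed`.
#'
#' @param n_per_class Records per class (>= 1).
#' @param seed Corpus seed.
#' @param record_s Record duration (s), default 20.
#' @param noise_snr_db Base SNR (dB), default 15.
#' @param heart_rate_range Range the per-record heart rate is drawn from.
#' @return `list(records, truths, manifest)`: records is a list of
#'   [pcg_record()], truths the matching ground-truth frames, and
#'   `manifest` a `data.frame(record_id, label)` in corpus order.
#' @export
generate_dataset <- function(n_per_class, seed = 1L, record_s = 20,
                             noise_snr_db = 15,
                             heart_rate_range = c(60, 100)) {
  stopifnot(n_per_class >= 1L)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  classes <- rep(pah_classes(), each = n_per_class)
  hrs <- stats::runif(length(classes), heart_rate_range[1L], heart_rate_range[2L])
  snrs <- noise_snr_db + stats::runif(length(classes), -2, 2)
  seeds <- sample.int(2^30, length(classes))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  records <- vector("list", length(classes))
  truths <- vector("list", length(classes))
  ids <- character(length(classes))
  for (i in seq_along(classes)) {
    sp <- synthetic_spec(classes[i], heart_rate_bpm = hrs[i],
                         record_s = record_s, noise_snr_db = snrs[i],
                         seed = seeds[i])
    g <- generate_record(sp)
    g$record$record_id <- sprintf("%s_%03d", classes[i], i)
    records[[i]] <- g$record
    truths[[i]] <- g$truth
    ids[i] <- g$record$record_id
  }
  list(records = records, truths = truths,
       manifest = data.frame(record_id = ids, label = classes,
                             stringsAsFactors = FALSE))
}
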