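## Shared fixtures: all built in code at test time.

## A pure tone as a pcg_record.
tone_record <- function(freq, dur_s = 1, rate = 2500, amp = 0.5, id = "tone") {
  t <- seq(0, dur_s - 1 / rate, by = 1 / rate)
  pcg_record(amp * sin(2 * pi * freq * t), rate, record_id = id)
}

## Deterministic small synthetic corpus for pipeline tests.
small_corpus <- function(n_per_class = 4L, seed = 11L, record_s = 20,
                         noise_snr_db = 15) {
  generate_dataset(n_per_class, seed = seed, record_s = record_s,
                   noise_snr_db = noise_snr_db)
}

## Small random PNCC-like images of three synthetic classes for CNN tests
## (16 x 8 keeps the unit tests fast; shape is configurable by contract).
toy_images <- function(n_per_class = 20L, seed = 4L, dim = c(16L, 8L)) {
  set.seed(seed)
  mk <- function(cl) {
    m <- matrix(abs(stats::rnorm(prod(dim), 0.5, 0.1)), dim[1L], dim[2L])
    if (cl == 2L) m[3:8, 2:5] <- m[3:8, 2:5] + 1
    if (cl == 3L) m[10:15, 4:7] <- m[10:15, 4:7] + 1
    m
  }
  cls <- rep(1:3, each = n_per_class)
  list(images = lapply(cls, mk), labels = pah_classes()[cls])
}
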