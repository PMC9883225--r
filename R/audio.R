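#' Construct a phonocardiogram record
#'
#' A `pcg_record` bundles a mono waveform with its sample rate, a record
#' identifier, and an optional class label. Amplitudes are dimensionless,
#' nominally in `[-1, 1]`.
#'
#' @param samples Numeric vector of amplitudes (non-empty, finite).
#' @param sample_rate Sampling rate in Hz (positive).
#' @param record_id Character scalar identifying the record.
#' @param label Optional class label, one of `"Normal"`, `"CHD"`, `"CHD-PAH"`.
#' @return An object of class `pcg_record`.
#' @export
pcg_record <- function(samples, sample_rate, record_id = "record", label = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("pcg_record: samples must be non-empty")
  if (any(!is.finite(samples))) stop("pcg_record: samples must be finite")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("pcg_record: sample_rate must be a positive scalar")
  if (!is.null(label)) label <- match.arg(label, pah_classes())
  structure(
    list(samples = samples, sample_rate = as.integer(round(sample_rate)),
         record_id = as.character(record_id), label = label),
    class = "pcg_record"
  )
}

#' @export
print.pcg_record <- function(x, ...) {
  cat(sprintf("<pcg_record '%s'>  %d samples @ %d Hz (%.2f s)%s\n",
              x$record_id, length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate,
              if (is.null(x$label)) "" else paste0("  label: ", x$label)))
  invisible(x)
}

#' Class labels recognised by the pipeline
#'
#' Order matters: it is the deterministic tie-break order used by record-level
#' voting when no strict majority exists.
#' @return Character vector `c("Normal", "CHD", "CHD-PAH")`.
#' @export
pah_classes <- function() c("Normal", "CHD", "CHD-PAH")

## ---- WAV (RIFF) I/O -------------------------------------------------------
## Minimal mono PCM16 / IEEE float32 reader and writer. Heart-sound recorders
## produce plain little-endian RIFF files; only the fmt and data chunks are
## interpreted, other chunks are skipped.

#' Read a mono WAV file as a `pcg_record`
#'
#' Supports 16-bit PCM and 32-bit IEEE float encodings. Integer samples are
#' scaled to `[-1, 1]` by `2^(bits-1)`. Stereo input is rejected: electronic
#' stethoscopes record a single channel.
#'
#' @param path Path to a readable WAV file.
#' @param record_id Identifier for the record; defaults to the file name.
#' @param label Optional class label.
#' @param expect_rate If non-`NULL`, fail unless the file's sample rate matches.
#' @return A [pcg_record()].
#' @export
load_record <- function(path, record_id = NULL, label = NULL, expect_rate = NULL) {
  if (!file.exists(path)) stop("load_record: file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("load_record: not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")  # total size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("load_record: not a WAVE file: ", path)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz + sz %% 2L)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1, size = 2, endian = "little"),
        n_channels   = readBin(body[3:4], "integer", 1, size = 2, endian = "little"),
        sample_rate  = readBin(body[5:8], "integer", 1, size = 4, endian = "little"),
        bits         = readBin(body[15:16], "integer", 1, size = 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (sz %% 2L) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", sz + sz %% 2L)  # skip unknown chunk (word aligned)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("load_record: missing fmt or data chunk: ", path)
  if (fmt$n_channels != 1L)
    stop("load_record: stereo input rejected (", fmt$n_channels, " channels)")

  if (fmt$audio_format == 1L && fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", length(data_raw) %/% 2L,
                 size = 2, signed = TRUE, endian = "little") / 32768
  } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
    x <- readBin(data_raw, "double", length(data_raw) %/% 4L,
                 size = 4, endian = "little")
  } else {
    stop("load_record: unsupported encoding (format ", fmt$audio_format,
         ", ", fmt$bits, " bits); expected PCM16 or float32")
  }
  if (length(x) == 0L) stop("load_record: zero-length audio: ", path)
  if (!is.null(expect_rate) && fmt$sample_rate != expect_rate)
    stop("load_record: sample rate ", fmt$sample_rate, " != expected ", expect_rate)

  if (is.null(record_id)) record_id <- sub("\\.wav$", "", basename(path), ignore.case = TRUE)
  lab <- label
  side <- paste0(sub("\\.wav$", "", path, ignore.case = TRUE), ".json")
  if (is.null(lab) && file.exists(side)) {
    meta <- jsonlite::fromJSON(side)
    if (!is.null(meta$label)) lab <- meta$label
    if (!is.null(meta$record_id)) record_id <- meta$record_id
  }
  pcg_record(x, fmt$sample_rate, record_id = record_id, label = lab)
}

#' Write a `pcg_record` to a mono WAV file
#'
#' @param record A [pcg_record()].
#' @param path Output path.
#' @param bits Either 16 (PCM, default) or 32 (IEEE float).
#' @param sidecar Write a JSON metadata sidecar (record_id, label, rate)?
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path, bits = 16L, sidecar = FALSE) {
  stopifnot(inherits(record, "pcg_record"), bits %in% c(16L, 32L))
  x <- record$samples
  rate <- record$sample_rate
  con <- file(path, "wb")
  on.exit(close(con))
  bytes_per <- bits %/% 8L
  data_sz <- length(x) * bytes_per
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_sz), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(as.integer(if (bits == 16L) 1L else 3L), con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_sz), con, size = 4, endian = "little")
  if (bits == 16L) {
    q <- as.integer(pmax(-32768, pmin(32767, round(x * 32768))))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(x, con, size = 4, endian = "little")
  }
  if (sidecar) {
    jsonlite::write_json(
      list(record_id = record$record_id, label = record$label, rate = rate),
      paste0(sub("\\.wav$", "", path, ignore.case = TRUE), ".json"),
      auto_unbox = TRUE, null = "null")
  }
  invisible(path)
}

## ---- Preprocessing --------------------------------------------------------

#' Resample a record to the working rate
#'
#' Anti-aliased polyphase FIR resampling (via [signal::resample()]). The
#' pipeline works at 2500 Hz: heart-sound content relevant to CHD-PAH lies
#' below 1000 Hz, so decimation from typical stethoscope rates (5000 Hz)
#' loses nothing.
#'
#' @param record A [pcg_record()].
#' @param target Target rate in Hz (default 2500).
#' @param allow_upsample Permit `target > sample_rate`? Default `FALSE`.
#' @return A [pcg_record()] at `target` Hz.
#' @export
resample_record <- function(record, target = 2500L, allow_upsample = FALSE) {
  stopifnot(inherits(record, "pcg_record"))
  fs <- record$sample_rate
  if (fs == target) return(record)
  if (fs < target && !allow_upsample)
    stop("resample_record: upsampling ", fs, " -> ", target,
         " Hz requested; set allow_upsample = TRUE to permit")
  g <- gcd_int(as.integer(target), as.integer(fs))
  p <- as.integer(target) %/% g
  q <- as.integer(fs) %/% g
  y <- signal::resample(record$samples, p, q)
  n_target <- round(length(record$samples) * target / fs)
  if (length(y) > n_target) y <- y[seq_len(n_target)]
  if (length(y) < n_target) y <- c(y, rep(0, n_target - length(y)))
  pcg_record(y, target, record_id = record$record_id, label = record$label)
}

gcd_int <- function(a, b) if (b == 0L) a else gcd_int(b, a %% b)

#' Preprocess a record for segmentation
#'
#' Resamples to the working rate and (by default) normalizes the amplitude to
#' a peak of 1, so that the adaptive energy thresholds are comparable across
#' recording gains.
#'
#' @param record A [pcg_record()].
#' @param working_rate Working sample rate in Hz, default 2500.
#' @param normalize Divide by `max(abs(samples))`? Default `TRUE`.
#' @return A [pcg_record()] at `working_rate`.
#' @export
preprocess_record <- function(record, working_rate = 2500L, normalize = TRUE) {
  rec <- resample_record(record, working_rate)
  if (normalize) {
    m <- max(abs(rec$samples))
    if (m > 0) rec$samples <- rec$samples / m
  }
  rec
}
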