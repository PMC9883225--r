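## Frequency-domain features of a cardiac cycle (256-point DFT) and of the
## S2 component (512-point DFT): spectral entropy, frequency center, peak
## frequency, plus framewise fundamental-frequency and dominant-frequency
## statistics computed over the whole segment.

#' Zero-padded magnitude spectrum (DC + positive half)
#'
#' Segments shorter than `n_points` are zero-padded (raising the frequency
#' resolution of the DFT grid); longer segments are truncated and the result
#' flagged. By conjugate symmetry of the real DFT only the DC bin and the
#' first half of the spectrum are retained (`n_points/2 + 1` values).
#'
#' @param segment Non-empty numeric waveform.
#' @param n_points DFT length, conventionally 256 for the cycle and 512 for S2.
#' @return Numeric vector of `n_points/2 + 1` magnitudes with attribute
#'   `truncated`.
#' @export
zero_padded_spectrum <- function(segment, n_points = 256L) {
  stopifnot(length(segment) > 0L, n_points >= 2L)
  truncated <- FALSE
  if (length(segment) > n_points) {
    segment <- segment[seq_len(n_points)]
    truncated <- TRUE
  } else if (length(segment) < n_points) {
    segment <- c(segment, rep(0, n_points - length(segment)))
  }
  mag <- Mod(stats::fft(segment))[seq_len(n_points %/% 2L + 1L)]
  attr(mag, "truncated") <- truncated
  mag
}

#' Spectral entropy, frequency center, and peak frequency
#'
#' Power (squared magnitude) is normalized to a probability distribution
#' `p`; entropy is `-sum(p log2 p)` in bits, the frequency center is
#' `sum(f p)` in Hz, and the peak frequency is the frequency of the largest
#' non-DC bin. An all-zero spectrum yields zeros, flagged.
#'
#' @param spectrum Non-negative magnitude spectrum (DC + half), as returned
#'   by [zero_padded_spectrum()].
#' @param rate Sample rate, Hz.
#' @return `list(entropy, center, peak_freq, flagged)`.
#' @export
spectral_summary <- function(spectrum, rate) {
  stopifnot(length(spectrum) > 0L, all(spectrum >= 0))
  n_fft <- (length(spectrum) - 1L) * 2L
  freqs <- (seq_along(spectrum) - 1L) * rate / n_fft
  pw <- spectrum^2
  tot <- sum(pw)
  if (tot == 0) return(list(entropy = 0, center = 0, peak_freq = 0, flagged = TRUE))
  p <- pw / tot
  nz <- p > 0
  entropy <- -sum(p[nz] * log2(p[nz]))
  center <- sum(freqs * p)
  peak_freq <- freqs[-1L][which.max(spectrum[-1L])]
  list(entropy = entropy, center = center, peak_freq = peak_freq, flagged = FALSE)
}

## Frame a signal with 50% overlap; returns a matrix (frame_len x n_frames).
frame_signal <- function(x, frame_len, hop) {
  n <- length(x)
  if (n < frame_len) return(matrix(x, ncol = 0, nrow = frame_len))
  starts <- seq(1L, n - frame_len + 1L, by = hop)
  vapply(starts, function(s) x[s:(s + frame_len - 1L)], numeric(frame_len))
}

#' Framewise fundamental-frequency statistics
#'
#' The fundamental is estimated per frame by the autocorrelation method:
#' the largest normalized autocorrelation peak in the 20-400 Hz lag band,
#' accepted only when the frame is above an energy floor and the normalized
#' peak exceeds a voicing threshold (0.3). Parabolic interpolation refines
#' the lag. Statistics are taken over accepted frames only.
#'
#' @param segment Numeric waveform.
#' @param rate Sample rate, Hz.
#' @param frame_s Frame length (s), default 0.05, 50% overlap.
#' @param f_min,f_max Search band (Hz).
#' @param voicing Normalized-autocorrelation acceptance threshold.
#' @return `list(mean_f0, min_f0, max_f0, n_frames_used, flagged)`; all
#'   zeros and `flagged = TRUE` when no frame yields an estimate.
#' @export
fundamental_stats <- function(segment, rate, frame_s = 0.05,
                              f_min = 20, f_max = 400, voicing = 0.3) {
  frame_len <- as.integer(round(frame_s * rate))
  stopifnot(length(segment) >= frame_len)
  frames <- frame_signal(segment, frame_len, max(1L, frame_len %/% 2L))
  lag_min <- max(2L, as.integer(floor(rate / f_max)))
  ## cap the longest admissible lag at 80% of the frame so the unbiased
  ## autocorrelation estimate stays stable
  lag_max <- min(as.integer(0.8 * frame_len), as.integer(ceiling(rate / f_min)))
  energy_floor <- 1e-4 * max(mean(segment^2), .Machine$double.eps)
  f0s <- numeric(0)
  for (j in seq_len(ncol(frames))) {
    fr <- frames[, j] - mean(frames[, j])
    if (mean(fr^2) < energy_floor) next
    ac <- as.numeric(stats::acf(fr, lag.max = lag_max, plot = FALSE,
                                demean = FALSE)$acf)
    ## undo the 1/n bias of the sample autocorrelation so long-lag
    ## (low-frequency) peaks are not penalized against short lags; cap the
    ## correction so residual noise at the longest lags is not blown up
    ac <- ac * pmin(frame_len / (frame_len - seq_along(ac) + 1L), 4)
    if (lag_max < lag_min + 1L) next
    seg_ac <- ac[(lag_min + 1L):(lag_max + 1L)]          # ac[k+1] = lag k
    top <- max(seg_ac)
    if (top < voicing) next
    ## shortest lag within 85% of the best peak: avoids the octave error of
    ## picking a period multiple
    i <- which(seg_ac >= 0.85 * top)[1L]
    lag <- lag_min + i - 1L
    ## parabolic refinement on the unbiased autocorrelation
    if (lag >= 2L && lag + 2L <= length(ac)) {
      y0 <- ac[lag]; y1 <- ac[lag + 1L]; y2 <- ac[lag + 2L]
      den <- y0 - 2 * y1 + y2
      d <- if (den != 0) 0.5 * (y0 - y2) / den else 0
      lag <- lag + max(-0.5, min(0.5, d))
    }
    f0s <- c(f0s, rate / lag)
  }
  if (length(f0s) == 0L)
    return(list(mean_f0 = 0, min_f0 = 0, max_f0 = 0, n_frames_used = 0L,
                flagged = TRUE))
  list(mean_f0 = mean(f0s), min_f0 = min(f0s), max_f0 = max(f0s),
       n_frames_used = length(f0s), flagged = FALSE)
}

#' Dominant frequencies over a segment
#'
#' Each Hamming-windowed frame's periodogram is searched for peaks above a
#' prominence floor (5% of the frame's maximal power); peak frequencies are
#' pooled across frames and deduplicated at bin resolution. Returns the
#' unique set and its mean/min/max/range.
#'
#' @param segment Numeric waveform.
#' @param rate Sample rate, Hz.
#' @param frame_s Frame length (s), default 0.05, 50% overlap.
#' @param floor_frac Per-frame peak floor as a fraction of max power.
#' @return `list(frequencies, mean_d, min_d, max_d, range_d, flagged)`.
#' @export
dominant_frequencies <- function(segment, rate, frame_s = 0.05,
                                 floor_frac = 0.05) {
  frame_len <- as.integer(round(frame_s * rate))
  if (length(segment) < frame_len) frame_len <- length(segment)
  frames <- frame_signal(segment, frame_len, max(1L, frame_len %/% 2L))
  if (ncol(frames) == 0L) frames <- matrix(segment[seq_len(frame_len)], ncol = 1L)
  w <- hamming_win(frame_len)
  half <- frame_len %/% 2L + 1L
  freqs <- (seq_len(half) - 1L) * rate / frame_len
  found <- numeric(0)
  for (j in seq_len(ncol(frames))) {
    psd <- Mod(stats::fft(frames[, j] * w))[seq_len(half)]^2
    top <- max(psd)
    if (top <= 0) next
    pk <- pracma::findpeaks(psd, minpeakheight = floor_frac * top)
    if (is.null(pk)) next
    found <- c(found, freqs[pk[, 2L]])
  }
  found <- sort(unique(found))
  if (length(found) == 0L)
    return(list(frequencies = numeric(0), mean_d = 0, min_d = 0, max_d = 0,
                range_d = 0, flagged = TRUE))
  list(frequencies = found, mean_d = mean(found), min_d = min(found),
       max_d = max(found), range_d = max(found) - min(found), flagged = FALSE)
}

#' Assemble the frequency-domain feature vector for one cycle
#'
#' Entropy/center/peak are computed on the fixed-length zero-padded DFT
#' (256 points for the cycle, 512 for S2); fundamental and dominant
#' frequency statistics use the framewise path over the full segment, so
#' that "measured in the whole signal" holds even for cycles longer than
#' the DFT length.
#'
#' @param cycle Cycle waveform.
#' @param s2 S2 waveform.
#' @param rate Sample rate, Hz.
#' @param n_cc,n_s2 DFT lengths (default 256 and 512).
#' @param higher_order Also emit spectral skewness and kurtosis (default
#'   `FALSE`; not part of the canonical feature set).
#' @return Named numeric vector with prefix-free names `es_cc, es_s2, c_cc,
#'   c_s2, pf_cc, pf_s2, af_*, minf_*, maxf_*, ad_*, mind_*, maxd_*, dd_*`.
#' @export
freq_features <- function(cycle, s2, rate, n_cc = 256L, n_s2 = 512L,
                          higher_order = FALSE) {
  sp_cc <- zero_padded_spectrum(cycle, n_cc)
  sp_s2 <- zero_padded_spectrum(s2, n_s2)
  sm_cc <- spectral_summary(sp_cc, rate)
  sm_s2 <- spectral_summary(sp_s2, rate)
  f0_cc <- fundamental_stats(cycle, rate)
  f0_s2 <- fundamental_stats(s2, rate)
  dm_cc <- dominant_frequencies(cycle, rate)
  dm_s2 <- dominant_frequencies(s2, rate)
  out <- c(es_cc = sm_cc$entropy, es_s2 = sm_s2$entropy,
           c_cc = sm_cc$center, c_s2 = sm_s2$center,
           pf_cc = sm_cc$peak_freq, pf_s2 = sm_s2$peak_freq,
           af_cc = f0_cc$mean_f0, af_s2 = f0_s2$mean_f0,
           minf_cc = f0_cc$min_f0, minf_s2 = f0_s2$min_f0,
           maxf_cc = f0_cc$max_f0, maxf_s2 = f0_s2$max_f0,
           ad_cc = dm_cc$mean_d, ad_s2 = dm_s2$mean_d,
           mind_cc = dm_cc$min_d, mind_s2 = dm_s2$min_d,
           maxd_cc = dm_cc$max_d, maxd_s2 = dm_s2$max_d,
           dd_cc = dm_cc$range_d, dd_s2 = dm_s2$range_d)
  if (higher_order) {
    out <- c(out,
             skew_cc = spectral_moment(sp_cc, rate, 3L),
             skew_s2 = spectral_moment(sp_s2, rate, 3L),
             kurt_cc = spectral_moment(sp_cc, rate, 4L),
             kurt_s2 = spectral_moment(sp_s2, rate, 4L))
  }
  out
}

spectral_moment <- function(spectrum, rate, order) {
  n_fft <- (length(spectrum) - 1L) * 2L
  freqs <- (seq_along(spectrum) - 1L) * rate / n_fft
  pw <- spectrum^2
  tot <- sum(pw)
  if (tot == 0) return(0)
  p <- pw / tot
  mu <- sum(freqs * p)
  sdv <- sqrt(sum((freqs - mu)^2 * p))
  if (sdv == 0) return(0)
  sum(((freqs - mu) / sdv)^order * p)
}
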