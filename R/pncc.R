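## Power-normalized feature images of cardiac cycles.
##
## The chain: pre-emphasis -> cycle-length-adaptive STFT with a fixed output
## frame count -> gammatone filterbank power -> medium-time power smoothing
## -> asymmetric noise-floor suppression with temporal masking -> spectral
## weight smoothing -> running mean-power normalization -> 1/15 power-law
## nonlinearity.  The output is a fixed n_frames x n_channels non-negative
## image, invariant to the overall amplitude of the input cycle.

#' PNCC configuration
#'
#' @param preemph_k Pre-emphasis coefficient (0.95).
#' @param n_frames_out Fixed number of output frames per cycle (default 64).
#' @param n_channels Number of filterbank channels L (default 40).
#' @param f_lo,f_hi Filterbank band edges in Hz (25-1000; heart-sound content
#'   lives below 1000 Hz).
#' @param smoothing_frames Medium-time half-window M (default 2).
#' @param freq_smooth_N Channel half-window N for weight smoothing (default 4).
#' @param mu_forget Mean-power forgetting factor (default 0.999).
#' @param asym_lambda_a,asym_lambda_b Asymmetric-filter forgetting factors
#'   (0.999 rising / 0.5 falling).
#' @param tm_lambda,tm_mu Temporal-masking forgetting factor (0.85) and
#'   masking factor (0.2).
#' @param excitation_c Excitation threshold multiplier on the noise floor (2).
#' @param power_exponent Rate-level nonlinearity exponent (1/15).
#' @param scale_k Arbitrary scale constant k in the normalization (default 1).
#' @return A list of class `pncc_config`.
#' @export
pncc_config <- function(preemph_k = 0.95, n_frames_out = 64L, n_channels = 40L,
                        f_lo = 25, f_hi = 1000, smoothing_frames = 2L,
                        freq_smooth_N = 4L, mu_forget = 0.999,
                        asym_lambda_a = 0.999, asym_lambda_b = 0.5,
                        tm_lambda = 0.85, tm_mu = 0.2, excitation_c = 2,
                        power_exponent = 1 / 15, scale_k = 1) {
  stopifnot(mu_forget > 0, mu_forget < 1, n_channels >= 4L)
  structure(as.list(environment()), class = "pncc_config")
}

#' Pre-emphasis filter
#'
#' `y[n] = x[n] - k x[n-1]` with `y[1] = x[1]`: a first-order high-pass that
#' lifts the upper band of the heart sound against low-frequency drift.
#'
#' @param x Non-empty numeric waveform.
#' @param k Coefficient, default 0.95.
#' @return Filtered waveform, same length.
#' @export
pre_emphasis <- function(x, k = 0.95) {
  stopifnot(length(x) > 0L)
  c(x[1L], x[-1L] - k * x[-length(x)])
}

#' Cycle-length-adaptive STFT with a fixed frame count
#'
#' Frame length and hop scale with the cycle length so that exactly
#' `n_frames_out` Hamming-windowed frames tile the cycle (50% nominal
#' overlap); each frame is DFT'd at the next power of two at or above the
#' frame length. This makes the downstream image shape independent of heart
#' rate.
#'
#' @param x Waveform (length >= `n_frames_out`).
#' @param n_frames_out Number of output frames.
#' @param rate Sample rate, Hz.
#' @return `list(spectra, freqs, n_fft, frame_len, hop)`; `spectra` is a
#'   complex matrix (`n_bins x n_frames_out`, half spectrum incl. DC).
#' @export
adaptive_stft <- function(x, n_frames_out = 64L, rate = 2500) {
  n <- length(x)
  if (n < n_frames_out) stop("adaptive_stft: cycle shorter than n_frames_out")
  if (n_frames_out == 1L) {
    frame_len <- n; hop <- n
  } else {
    hop <- max(1L, n %/% n_frames_out)
    frame_len <- min(n, 2L * hop)
  }
  n_fft <- 2L^ceiling(log2(max(frame_len, 8L)))
  w <- hamming_win(frame_len)
  half <- n_fft %/% 2L + 1L
  frames <- matrix(0, nrow = n_fft, ncol = n_frames_out)
  for (m in seq_len(n_frames_out)) {
    s <- (m - 1L) * hop + 1L
    e <- min(n, s + frame_len - 1L)
    frames[seq_len(e - s + 1L), m] <- x[s:e] * w[seq_len(e - s + 1L)]
  }
  spec <- stats::mvfft(frames)[seq_len(half), , drop = FALSE]
  list(spectra = spec, freqs = (seq_len(half) - 1L) * rate / n_fft,
       n_fft = n_fft, frame_len = frame_len, hop = hop)
}

#' Gammatone filterbank weights on a DFT grid
#'
#' Squared-magnitude gammatone (order 4) frequency responses with center
#' frequencies ERB-spaced over `[f_lo, f_hi]`, evaluated on the half-spectrum
#' grid and renormalized so each channel satisfies `sum_k |H_l(k)|^2 = 1`
#' exactly.
#'
#' @param freqs Frequency grid (Hz) of the half spectrum.
#' @param n_channels Number of channels L.
#' @param f_lo,f_hi Band edges (Hz).
#' @return Matrix `n_bins x n_channels` of squared magnitudes, columns
#'   summing to 1.
#' @export
gammatone_fbank <- function(freqs, n_channels = 40L, f_lo = 25, f_hi = 1000) {
  erb <- function(f) 21.4 * log10(1 + 0.00437 * f)
  erb_inv <- function(e) (10^(e / 21.4) - 1) / 0.00437
  centers <- erb_inv(seq(erb(f_lo), erb(f_hi), length.out = n_channels))
  H2 <- vapply(centers, function(fc) {
    b <- 1.019 * (24.7 + 0.108 * fc)            # gammatone bandwidth
    (1 + ((freqs - fc) / b)^2)^(-4)             # |H|^2 of order-4 gammatone
  }, numeric(length(freqs)))
  sweep(H2, 2L, colSums(H2), "/")
}

#' Short-time filterbank power
#'
#' `P[m, l] = sum_k |X[m, k]|^2 |H_l(k)|^2` per frame and channel. With the
#' channel normalization of [gammatone_fbank()], a white spectrum
#' (`|X| = 1`) yields `P = 1` in every channel.
#'
#' @param spectra Complex half-spectrum matrix (`n_bins x n_frames`).
#' @param fbank Filterbank weights (`n_bins x n_channels`, squared
#'   magnitudes).
#' @return Power matrix `n_frames x n_channels`, non-negative.
#' @export
filterbank_power <- function(spectra, fbank) {
  stopifnot(nrow(spectra) == nrow(fbank))
  t(crossprod(fbank, Mod(spectra)^2))
}

#' Medium-time power
#'
#' Running mean of `P` over `2M + 1` frames; at the sequence edges the window
#' shrinks to the available frames rather than zero-padding, so edge frames
#' are not darkened.
#'
#' @param P Power matrix (`n_frames x n_channels`).
#' @param M Half-window in frames, default 2.
#' @return Smoothed matrix, same shape.
#' @export
medium_time_power <- function(P, M = 2L) {
  n <- nrow(P)
  Q <- matrix(0, n, ncol(P))
  for (m in seq_len(n)) {
    lo <- max(1L, m - M); hi <- min(n, m + M)
    Q[m, ] <- colMeans(P[lo:hi, , drop = FALSE])
  }
  Q
}

## First-order asymmetric lowpass: rises with factor la, falls with lb.
asym_filter <- function(q, la, lb, init = NULL) {
  n <- length(q)
  out <- numeric(n)
  prev <- if (is.null(init)) 0.9 * q[1L] else init
  for (m in seq_len(n)) {
    prev <- if (q[m] >= prev) la * prev + (1 - la) * q[m]
            else               lb * prev + (1 - lb) * q[m]
    out[m] <- prev
  }
  out
}

#' Asymmetric noise suppression with temporal masking
#'
#' Per channel, an asymmetric first-order filter (slow rise, fast fall)
#' tracks the noise floor of the medium-time power; the floor is subtracted
#' and the result half-wave rectified. A temporal-masking stage suppresses
#' trailing energy behind an onset peak, and non-excitation frames (power
#' below `excitation_c` times the floor) fall back to the smoothed floor of
#' the rectified signal. Heart-sound bursts change much faster than ambient
#' noise, which is what makes this spectral-subtraction scheme effective.
#'
#' @param Q Medium-time power (`n_frames x n_channels`).
#' @param config A [pncc_config()].
#' @return Suppressed power matrix `R`, same shape, non-negative.
#' @export
asymmetric_noise_suppression <- function(Q, config = pncc_config()) {
  n <- nrow(Q); L <- ncol(Q)
  R <- matrix(0, n, L)
  la <- config$asym_lambda_a; lb <- config$asym_lambda_b
  lt <- config$tm_lambda; mt <- config$tm_mu
  for (l in seq_len(L)) {
    q <- Q[, l]
    floor_le <- asym_filter(q, la, lb)
    q0 <- pmax(q - floor_le, 0)
    floor_f <- asym_filter(q0, la, lb)
    ## temporal masking on the rectified excitation
    rsp <- numeric(n)
    peak <- 0
    for (m in seq_len(n)) {
      if (q0[m] >= lt * peak) {
        rsp[m] <- q0[m]
        peak <- q0[m]
      } else {
        rsp[m] <- mt * peak
        peak <- lt * peak
      }
    }
    excited <- q >= config$excitation_c * floor_le
    R[, l] <- ifelse(excited, rsp, floor_f)
  }
  pmax(R, 0)
}

#' Spectral weight smoothing
#'
#' The noise-suppression transfer ratio `R/Q` is averaged over neighbouring
#' channels (`l' in [l-N, l+N]`, clipped at the band edges) and the smoothed
#' transfer function modulates the original short-time power:
#' `T[m, l] = P[m, l] * mean(R/Q)`. Channels whose medium-time power is
#' below a relative floor contribute a ratio of 0.
#'
#' @param R Suppressed medium-time power.
#' @param Q Medium-time power.
#' @param P Short-time power.
#' @param N Channel half-window, default 4.
#' @return Weighted power `T`, same shape as `P`.
#' @export
spectral_weight_smoothing <- function(R, Q, P, N = 4L) {
  stopifnot(all(dim(R) == dim(Q)), all(dim(Q) == dim(P)))
  L <- ncol(Q)
  eps <- 1e-12 * max(Q)
  ratio <- ifelse(Q > eps, R / pmax(Q, eps), 0)
  S <- matrix(0, nrow(Q), L)
  for (l in seq_len(L)) {
    l1 <- max(l - N, 1L); l2 <- min(l + N, L)
    S[, l] <- rowMeans(ratio[, l1:l2, drop = FALSE])
  }
  P * S
}

#' Running mean-power normalization and rate-level nonlinearity
#'
#' The per-frame mean power is tracked with a forgetting factor
#' (`mu[m] = lambda mu[m-1] + (1 - lambda)/L sum_l T[m, l]`, initialized at
#' the first frame's channel mean to avoid a startup transient on short
#' cycles), the power is divided by it (`U = k T / mu`), and compressed
#' with the auditory power law `V = U^(1/15)`.
#'
#' @param T_mat Weighted power (`n_frames x n_channels`).
#' @param config A [pncc_config()].
#' @return Matrix `V`, same shape, non-negative; attribute `flagged` is
#'   `TRUE` if the mean-power floor guard engaged.
#' @export
power_normalize <- function(T_mat, config = pncc_config()) {
  lam <- config$mu_forget
  L <- ncol(T_mat)
  n <- nrow(T_mat)
  mu <- numeric(n)
  mu_prev <- mean(T_mat[1L, ])
  flagged <- FALSE
  eps <- .Machine$double.xmin
  for (m in seq_len(n)) {
    mu_prev <- lam * mu_prev + (1 - lam) * mean(T_mat[m, ])
    mu[m] <- mu_prev
  }
  if (any(mu <= 0)) { flagged <- TRUE; mu <- pmax(mu, eps) }
  U <- config$scale_k * T_mat / mu
  V <- U^config$power_exponent
  attr(V, "flagged") <- flagged
  V
}

#' Power-normalized feature image of one cardiac cycle
#'
#' Runs the whole chain and returns the fixed-shape image
#' (`n_frames_out x n_channels`). The image is invariant to amplitude
#' scaling of the input cycle, the property that makes it robust to
#' recording gain.
#'
#' @param cycle Cycle waveform at the working rate.
#' @param config A [pncc_config()].
#' @param rate Sample rate, Hz.
#' @return Non-negative numeric matrix `n_frames_out x n_channels` of class
#'   `pncc_image`.
#' @export
pncc_image <- function(cycle, config = pncc_config(), rate = 2500) {
  y <- pre_emphasis(cycle, config$preemph_k)
  st <- adaptive_stft(y, config$n_frames_out, rate)
  fb <- gammatone_fbank(st$freqs, config$n_channels, config$f_lo, config$f_hi)
  P <- filterbank_power(st$spectra, fb)
  Q <- medium_time_power(P, config$smoothing_frames)
  R <- asymmetric_noise_suppression(Q, config)
  T_mat <- spectral_weight_smoothing(R, Q, P, config$freq_smooth_N)
  V <- power_normalize(T_mat, config)
  structure(unclass(V), class = c("pncc_image", "matrix"),
            flagged = attr(V, "flagged"))
}
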