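## Time-domain features of a cardiac cycle and its S2 component.
## On auscultation, CHD-PAH presents as a hyperactive, split S2, so most
## features target S2 intensity and the A2-P2 peak geometry.

#' Heart-sound intensity of a segment
#'
#' Sum of squared amplitudes (no 1/n factor): reflects valve activity and
#' myocardial contractility and is the primary S2-accentuation feature.
#'
#' @param segment Non-empty numeric waveform.
#' @return Scalar intensity.
#' @export
intensity <- function(segment) {
  stopifnot(length(segment) > 0L)
  sum(segment^2)
}

#' Largest and second-largest morphological peaks of a segment
#'
#' Peaks are found on the rectified waveform smoothed with a `smooth_ms`
#' moving average, so that "second maximum" means a second morphological
#' lobe (e.g. P2 after A2), not an adjacent sample of the same oscillation.
#' The second peak must be a local maximum at least `min_sep_ms` away from
#' the global maximum.
#'
#' @param segment Numeric waveform.
#' @param rate Sample rate, Hz.
#' @param min_sep_ms Minimum peak separation (ms), default 20.
#' @param smooth_ms Smoothing window (ms), default 10.
#' @param sentinel Phase-difference value reported when no second peak
#'   exists (default 0).
#' @return `list(max_val, second_val, phase_diff_s, flagged)`; `flagged` is
#'   `TRUE` when no admissible second peak exists.
#' @export
peak_pair <- function(segment, rate, min_sep_ms = 20, smooth_ms = 10,
                      sentinel = 0) {
  n <- length(segment)
  min_sep <- max(1L, as.integer(round(min_sep_ms / 1000 * rate)))
  stopifnot(n > 2L * min_sep)
  w <- max(1L, as.integer(round(smooth_ms / 1000 * rate)))
  env <- as.numeric(stats::filter(abs(segment), rep(1 / w, w), sides = 2))
  env[is.na(env)] <- 0
  i_max <- which.max(env)
  ## local maxima of the smoothed envelope
  locs <- which(diff(sign(diff(env))) < 0) + 1L
  locs <- locs[abs(locs - i_max) >= min_sep]
  if (length(locs) == 0L) {
    return(list(max_val = env[i_max], second_val = 0,
                phase_diff_s = sentinel, flagged = TRUE))
  }
  i2 <- locs[which.max(env[locs])]
  list(max_val = env[i_max], second_val = env[i2],
       phase_diff_s = abs(i_max - i2) / rate, flagged = FALSE)
}

#' Assemble the time-domain feature vector for one cycle
#'
#' Intensities, durations, their S2/cycle ratios, the two largest peak
#' amplitudes of cycle and S2, and the peak-to-second-peak phase difference
#' (the A2-P2 split surrogate) for S2 and, optionally, the whole cycle.
#'
#' @param cycle Cycle waveform.
#' @param s2 S2 sub-segment waveform (a sub-segment of `cycle`).
#' @param rate Sample rate, Hz.
#' @param include_pos_cc Include the whole-cycle phase difference
#'   (default `TRUE`).
#' @return Named numeric vector with elements `i_cc, i_s2, i_ratio, l_cc,
#'   l_s2, l_ratio, m_cc, m_s2, m2_cc, m2_s2, pos_s2` and (optionally)
#'   `pos_cc`.
#' @export
time_features <- function(cycle, s2, rate, include_pos_cc = TRUE) {
  i_cc <- intensity(cycle)
  i_s2 <- intensity(s2)
  if (i_cc == 0) stop("time_features: zero-intensity cycle")
  l_cc <- length(cycle) / rate
  l_s2 <- length(s2) / rate
  p_s2 <- peak_pair(s2, rate)
  out <- c(i_cc = i_cc, i_s2 = i_s2, i_ratio = i_s2 / i_cc,
           l_cc = l_cc, l_s2 = l_s2, l_ratio = l_s2 / l_cc,
           m_cc = max(abs(cycle)), m_s2 = p_s2$max_val,
           m2_cc = NA_real_, m2_s2 = p_s2$second_val,
           pos_s2 = p_s2$phase_diff_s)
  p_cc <- peak_pair(cycle, rate)
  out["m_cc"] <- p_cc$max_val
  out["m2_cc"] <- p_cc$second_val
  if (include_pos_cc) out <- c(out, pos_cc = p_cc$phase_diff_s)
  out
}
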