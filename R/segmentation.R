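## Double-threshold adaptive segmentation of heart sounds.
##
## S1 and S2 carry far more short-time energy than systole and diastole, and
## have a lower, more concentrated spectrum than broadband murmurs.  Two
## per-frame envelopes (short-time energy and spectral spread) are thresholded
## with histogram-derived adaptive thresholds, the two binary masks are
## AND-combined, nearby runs are merged, and the surviving components are
## labelled S1/S2 from the inter-component gap structure (the longest gap in a
## cycle is always the diastole, from the end of S2 to the start of the next
## S1).

#' Per-frame short-time energy and spectral spread envelopes
#'
#' The record is cut into non-overlapping frames of `window_s` seconds.
#' Energy is the mean squared amplitude of the raw frame. Spectral spread is
#' the standard deviation (Hz) of the Hamming-windowed frame's power
#' spectrum about its centroid (the frequency center of mass); an all-zero
#' frame has spread 0 by convention. Power weighting makes the statistic
#' sharply bimodal across frames: tonal heart-sound bursts concentrate their
#' power in a few low-frequency bins (small spread), broadband noise does
#' not.
#'
#' @param record A [pcg_record()] at the working rate.
#' @param window_s Frame length in seconds (default 0.1).
#' @return A list of class `pcg_envelopes` with `energies`, `spreads`,
#'   `frame_len` (samples), `hop` (== `frame_len`), and `rate`.
#' @export
compute_envelopes <- function(record, window_s = 0.1) {
  stopifnot(inherits(record, "pcg_record"))
  fs <- record$sample_rate
  frame_len <- as.integer(round(window_s * fs))
  x <- record$samples
  n_frames <- length(x) %/% frame_len
  if (n_frames < 1L) stop("compute_envelopes: record shorter than one frame")
  idx <- matrix(seq_len(n_frames * frame_len), nrow = frame_len)
  frames <- matrix(x[idx], nrow = frame_len)

  energies <- colMeans(frames^2)

  w <- hamming_win(frame_len)
  spec <- Mod(stats::mvfft(frames * w))^2
  half <- frame_len %/% 2L + 1L
  spec <- spec[seq_len(half), , drop = FALSE]
  freqs <- (seq_len(half) - 1L) * fs / frame_len
  tot <- colSums(spec)
  cent <- ifelse(tot > 0, colSums(freqs * spec) / tot, 0)
  dev2 <- (matrix(freqs, nrow = half, ncol = n_frames) -
             matrix(cent, nrow = half, ncol = n_frames, byrow = TRUE))^2
  spreads <- ifelse(tot > 0, sqrt(colSums(dev2 * spec) / tot), 0)

  structure(list(energies = as.numeric(energies), spreads = as.numeric(spreads),
                 frame_len = frame_len, hop = frame_len, rate = fs),
            class = "pcg_envelopes")
}

hamming_win <- function(n) {
  if (n == 1L) return(1)
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

#' Histogram-based adaptive threshold
#'
#' Builds a histogram of the envelope values, smooths the counts (two passes
#' of a 5-bin moving average), locates the local maxima, and takes `M1` and
#' `M2` as the bin-center positions of the highest and second-highest
#' maxima. The threshold is the weighted mean `T = (W * M1 + M2) / (W + 1)`:
#' since background frames dominate any heart-sound record, `M1` is the
#' background mode and `W` biases the threshold toward it (the sensitive
#' setting); `W = 0` gives `M2`, `W -> Inf` gives `M1`.
#'
#' @param values Non-empty numeric vector (an envelope sequence).
#' @param W Weight on the first mode (default 5).
#' @param n_bins Number of histogram bins (default 50, minimum 3).
#' @return A numeric threshold with attributes `M1`, `M2`, and `fallback`
#'   (`TRUE` when fewer than two local maxima exist and the threshold falls
#'   back to `mean + 0.5 * sd`).
#' @export
adaptive_threshold <- function(values, W = 5, n_bins = 50L) {
  stopifnot(length(values) > 0L, n_bins >= 3L)
  rng <- range(values)
  if (diff(rng) == 0) {
    t <- rng[1] + 0.0
    attributes(t) <- list(M1 = rng[1], M2 = rng[1], fallback = TRUE)
    return(t)
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- graphics::hist(values, breaks = breaks, plot = FALSE)$counts
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  ## smooth enough that sampling jitter inside one mode does not spawn
  ## spurious local maxima: two passes of a 5-bin moving average with
  ## edge-replicated padding
  sm <- as.numeric(counts)
  for (pass in 1:2) {
    padded <- c(rep(sm[1L], 2L), sm, rep(sm[length(sm)], 2L))
    sm <- vapply(seq_along(sm), function(i) mean(padded[i:(i + 4L)]), numeric(1))
  }
  ## local maxima: strictly above one neighbour, not below the other
  maxima <- which(vapply(seq_along(sm), function(i) {
    l <- if (i > 1L) sm[i - 1L] else -Inf
    r <- if (i < length(sm)) sm[i + 1L] else -Inf
    sm[i] > 0 && ((sm[i] > l && sm[i] >= r) || (sm[i] >= l && sm[i] > r))
  }, logical(1)))
  ## collapse plateaus of equal smoothed height to their first bin
  if (length(maxima) > 1L) {
    keep <- c(TRUE, diff(maxima) > 1L | sm[maxima[-1]] != sm[maxima[-length(maxima)]])
    maxima <- maxima[keep]
  }
  ## distinct modes must be separated; drop maxima within 2 bins of the
  ## previous kept one
  if (length(maxima) > 1L) {
    kept <- maxima[1L]
    for (m in maxima[-1L]) if (m - kept[length(kept)] > 2L) kept <- c(kept, m)
    maxima <- kept
  }
  if (length(maxima) < 2L) {
    t <- mean(values) + 0.5 * stats::sd(values)
    attributes(t) <- list(M1 = NA_real_, M2 = NA_real_, fallback = TRUE)
    return(t)
  }
  ## rank the modes by smoothed height: M1 = dominant mode, M2 = runner-up
  ord <- maxima[order(-sm[maxima])]
  M1 <- centers[ord[1L]]
  M2 <- centers[ord[2L]]
  t <- (W * M1 + M2) / (W + 1)
  attributes(t) <- list(M1 = M1, M2 = M2, fallback = FALSE)
  t
}

#' Detect candidate heart-sound components
#'
#' Frames whose energy and spectral spread both pass their thresholds are
#' candidates; adjacent candidate runs separated by less than `merge_ms`
#' milliseconds are merged (strictly less: a gap of exactly `merge_ms` stays
#' split). Surviving runs are mapped back to half-open sample intervals and,
#' optionally, refined to 10 ms resolution with a fine energy envelope so
#' that component edges are not quantized to the coarse 0.1 s frame.
#'
#' @param env A `pcg_envelopes` object.
#' @param t_energy,t_spread Thresholds from [adaptive_threshold()].
#' @param merge_ms Merge distance in milliseconds (default 50).
#' @param spread_direction `"<="` (default: heart-sound frames concentrate
#'   their spectrum at low frequencies, so a *small* spectral spread marks a
#'   heart sound and broadband noise/murmur frames are rejected) or `">="`
#'   (the literal direction of the detection rule as printed; fragile when
#'   the threshold lands above the burst mode).
#' @param refine Refine edges at 10 ms resolution (default `TRUE`).
#' @param samples Raw samples, required when `refine = TRUE`.
#' @return `data.frame(start, end)` of 0-based half-open sample intervals,
#'   possibly empty.
#' @export
detect_components <- function(env, t_energy, t_spread, merge_ms = 50,
                              spread_direction = c("<=", ">="),
                              refine = TRUE, samples = NULL) {
  stopifnot(inherits(env, "pcg_envelopes"))
  spread_direction <- match.arg(spread_direction)
  flag1 <- env$energies >= t_energy
  flag2 <- if (spread_direction == ">=") env$spreads >= t_spread else env$spreads <= t_spread
  cand <- flag1 & flag2
  runs <- logical_runs(cand)
  if (nrow(runs) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))

  ## frame -> sample coordinates (half-open)
  comp <- data.frame(start = (runs$start - 1L) * env$hop,
                     end   = runs$end * env$hop)
  comp <- merge_components(comp, merge_ms, env$rate)

  if (refine) {
    if (is.null(samples)) stop("detect_components: refine needs samples")
    comp <- refine_edges(comp, samples, env, t_energy)
    comp <- merge_components(comp, merge_ms, env$rate)
  }
  comp
}

logical_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Merge nearby component intervals
#'
#' Adjacent intervals whose gap in seconds is strictly less than
#' `merge_ms / 1000` are merged. Idempotent: a second application changes
#' nothing.
#'
#' @param comp `data.frame(start, end)` in samples, sorted, non-overlapping.
#' @param merge_ms Merge distance, milliseconds.
#' @param rate Sample rate, Hz.
#' @return Merged `data.frame(start, end)`.
#' @export
merge_components <- function(comp, merge_ms, rate) {
  if (nrow(comp) <= 1L) return(comp)
  gap_limit <- merge_ms / 1000
  out_s <- comp$start[1L]; out_e <- comp$end[1L]
  res <- list()
  for (i in 2:nrow(comp)) {
    gap <- (comp$start[i] - out_e) / rate
    if (gap < gap_limit) {
      out_e <- max(out_e, comp$end[i])
    } else {
      res[[length(res) + 1L]] <- c(out_s, out_e)
      out_s <- comp$start[i]; out_e <- comp$end[i]
    }
  }
  res[[length(res) + 1L]] <- c(out_s, out_e)
  m <- do.call(rbind, res)
  data.frame(start = m[, 1L], end = m[, 2L])
}

## Sub-frame refinement: the coarse envelope quantizes edges to 0.1 s,
## coarser than S2 itself, and cannot resolve a short systole at high heart
## rates (S1 and S2 fuse into one coarse run).  Within each coarse component
## (padded by one coarse frame) the energy envelope is re-evaluated on 10 ms
## sub-frames against the same threshold — mean power is frame-length
## invariant, so the coarse threshold applies — and the crossing runs become
## the refined components.  Sub-50 ms gaps inside one burst re-merge
## afterwards; runs shorter than `min_dur_s` are discarded as noise flickers.
refine_edges <- function(comp, samples, env, t_energy, min_dur_s = 0.02) {
  fine_len <- max(1L, as.integer(round(0.010 * env$rate)))
  n <- length(samples)
  n_fine <- n %/% fine_len
  if (n_fine < 1L) return(comp)
  hot <- logical(n_fine)
  pw_cache <- rep(NA_real_, n_fine)
  for (i in seq_len(nrow(comp))) {
    lo <- max(0L, comp$start[i] - env$frame_len)
    hi <- min(n, comp$end[i] + env$frame_len)
    ks <- (lo %/% fine_len):min(n_fine - 1L, (hi - 1L) %/% fine_len)
    for (k in ks) {
      if (is.na(pw_cache[k + 1L])) {
        a <- k * fine_len + 1L; b <- min(n, (k + 1L) * fine_len)
        pw_cache[k + 1L] <- mean(samples[a:b]^2)
      }
      if (pw_cache[k + 1L] >= t_energy) hot[k + 1L] <- TRUE
    }
  }
  runs <- logical_runs(hot)
  if (nrow(runs) == 0L) return(comp)
  out <- data.frame(start = (runs$start - 1L) * fine_len,
                    end = pmin(n, runs$end * fine_len))
  out[(out$end - out$start) / env$rate >= min_dur_s, , drop = FALSE]
}

#' Label components as S1/S2 and assemble cardiac cycles
#'
#' The diastole is the longest interval between two adjacent components (end
#' of S2 to start of the next S1), so gaps are split into long (diastolic)
#' and short (systolic) at the midpoint of the observed gap range; each long
#' gap labels its left neighbour S2 and its right neighbour S1 — which
#' reproduces, cycle by cycle, the rule of anchoring at the maximal gap and
#' alternating labels outward, while confining the damage of a spurious
#' component to its own cycle. Only complete S1->systole->S2->diastole cycles
#' that pass physiologic validation (duration within `min_cycle_s`..
#' `max_cycle_s` and systole shorter than diastole) are emitted.
#'
#' @param comp `data.frame(start, end)` of components, sample coordinates.
#' @param record_len Record length in samples.
#' @param rate Sample rate, Hz.
#' @param min_cycle_s,max_cycle_s Physiologic cycle-duration bounds (s).
#' @return `data.frame(cycle, label, start, end)` with labels
#'   `s1`, `systole`, `s2`, `diastole` (four rows per cycle), or a zero-row
#'   frame with attribute `unsegmentable = TRUE` when labelling fails.
#' @export
label_components <- function(comp, record_len, rate = 2500,
                             min_cycle_s = 0.4, max_cycle_s = 1.5) {
  unseg <- function() {
    out <- data.frame(cycle = integer(0), label = character(0),
                      start = integer(0), end = integer(0))
    attr(out, "unsegmentable") <- TRUE
    out
  }
  if (nrow(comp) < 4L) return(unseg())
  n <- nrow(comp)
  gaps <- comp$start[-1L] - comp$end[-n]             # samples, length n-1
  if (any(gaps < 0)) return(unseg())
  gr <- range(gaps)
  if (diff(gr) / rate < 0.05) return(unseg())        # no systole/diastole contrast
  ## split gaps into short (systolic) and long (diastolic): 2-means on the
  ## log duration, initialized at the quartiles so the clusters track the
  ## two bulk modes; an outlier gap from a missed component joins the long
  ## cluster without dragging the boundary
  lg <- log(pmax(gaps, 1))
  init <- stats::quantile(lg, c(0.25, 0.75), names = FALSE)
  if (diff(init) < 1e-9) init <- range(lg)
  km <- tryCatch(
    stats::kmeans(lg, centers = matrix(init), algorithm = "Lloyd",
                  iter.max = 100L),
    error = function(e) NULL)
  if (is.null(km)) return(unseg())
  long_cl <- which.max(km$centers)
  if (exp(abs(diff(km$centers))) < 1.25) return(unseg())  # modes too close
  is_diast <- km$cluster == long_cl
  if (!any(is_diast) || all(is_diast)) return(unseg())

  ## S1 indices: components immediately after a diastolic gap
  s1_idx <- which(is_diast) + 1L
  cycles <- list()
  ci <- 0L
  for (j in seq_along(s1_idx)) {
    i1 <- s1_idx[j]
    nxt <- s1_idx[s1_idx > i1]
    if (length(nxt) == 0L) break
    i_next <- nxt[1L]
    ## a clean cycle has exactly one component (S2) between this S1 and the next
    if (i_next - i1 != 2L) next
    i2 <- i1 + 1L
    sys_len <- (comp$start[i2] - comp$end[i1]) / rate
    dia_len <- (comp$start[i_next] - comp$end[i2]) / rate
    dur <- (comp$start[i_next] - comp$start[i1]) / rate
    if (dur < min_cycle_s || dur > max_cycle_s) next
    if (sys_len >= dia_len) next
    ci <- ci + 1L
    cycles[[ci]] <- data.frame(
      cycle = ci,
      label = c("s1", "systole", "s2", "diastole"),
      start = c(comp$start[i1], comp$end[i1], comp$start[i2], comp$end[i2]),
      end   = c(comp$end[i1], comp$start[i2], comp$end[i2], comp$start[i_next])
    )
  }
  if (ci == 0L) return(unseg())
  out <- do.call(rbind, cycles)
  attr(out, "unsegmentable") <- FALSE
  out
}

#' Segment a record into annotated cardiac cycles
#'
#' Runs the full double-threshold chain: envelopes, adaptive thresholds,
#' AND-combination, merging, optional edge refinement, and physiological
#' labelling.
#'
#' @param record A [pcg_record()] at the working rate.
#' @param window_s Envelope frame length (s), default 0.1.
#' @param W Threshold weight, default 5.
#' @param merge_ms Merge distance (ms), default 50.
#' @param spread_direction See [detect_components()].
#' @param refine Sub-frame edge refinement, default `TRUE`.
#' @return The annotation `data.frame` of [label_components()], with the
#'   detected components as attribute `components` and thresholds as
#'   attribute `thresholds`.
#' @export
segment_record <- function(record, window_s = 0.1, W = 5, merge_ms = 50,
                           spread_direction = "<=", refine = TRUE) {
  env <- compute_envelopes(record, window_s)
  t_e <- adaptive_threshold(env$energies, W)
  t_s <- adaptive_threshold(env$spreads, W)
  comp <- detect_components(env, as.numeric(t_e), as.numeric(t_s),
                            merge_ms = merge_ms,
                            spread_direction = spread_direction,
                            refine = refine, samples = record$samples)
  ann <- label_components(comp, length(record$samples), record$sample_rate)
  attr(ann, "components") <- comp
  attr(ann, "thresholds") <- c(energy = as.numeric(t_e), spread = as.numeric(t_s))
  ann
}

#' Extract cycle and S2 waveforms from an annotation
#'
#' Each complete cardiac cycle and its S2 component are saved separately —
#' the cycle is the unit of all downstream feature extraction.
#'
#' @param record A [pcg_record()].
#' @param annotation Annotation `data.frame` from [segment_record()] or
#'   ground truth (`cycle`, `label`, `start`, `end` in samples, 0-based
#'   half-open).
#' @return A list with one element per cycle: `list(cycle = numeric,
#'   s2 = numeric, offset = start sample, s2_offset = s2 start sample)`.
#'   Empty list for an unsegmentable record.
#' @export
extract_cycles <- function(record, annotation) {
  stopifnot(inherits(record, "pcg_record"))
  if (nrow(annotation) == 0L) return(list())
  x <- record$samples
  out <- lapply(split(annotation, annotation$cycle), function(a) {
    cs <- min(a$start); ce <- max(a$end)
    s2 <- a[a$label == "s2", , drop = FALSE]
    if (nrow(s2) != 1L) return(NULL)
    list(cycle = x[(cs + 1L):ce],
         s2 = x[(s2$start + 1L):s2$end],
         offset = cs, s2_offset = s2$start)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  names(out) <- NULL
  out
}

#' Write a cycle annotation as CSV
#'
#' Columns: `record_id, cycle_index, label, start_s, end_s`.
#' @param annotation Annotation `data.frame` (sample coordinates).
#' @param record_id Record identifier.
#' @param path Output CSV path.
#' @param rate Sample rate (Hz) used to convert to seconds.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, record_id, path, rate = 2500) {
  df <- data.frame(record_id = record_id,
                   cycle_index = annotation$cycle,
                   label = annotation$label,
                   start_s = annotation$start / rate,
                   end_s = annotation$end / rate)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
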