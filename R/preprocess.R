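#' Zero-phase low-pass filter and linear detrend
#'
#' Applies a 6th-order Butterworth low-pass filter (default cutoff 10 Hz)
#' forward and backward, so the net magnitude response is the squared
#' Butterworth response `|H(f)|^2 = (1 + (f/fc)^12)^-1` squared once more by
#' the second pass, with zero phase distortion; then removes the best-fit
#' straight line. Run per session, before beat segmentation.
#'
#' @param record A [ppg_record()], or a numeric vector if `fs` is given.
#' @param fs Sampling rate in Hz (only when `record` is a bare vector).
#' @param cutoff Cutoff frequency in Hz.
#' @param order Filter order.
#' @return Numeric vector of filtered, detrended samples (same length).
#' @export
lowpass_detrend <- function(record, fs = NULL, cutoff = 10, order = 6) {
  if (inherits(record, "ppg_record")) {
    x <- record$samples
    fs <- record$fs
  } else {
    x <- as.numeric(record)
    if (is.null(fs)) stop("`fs` is required for a bare sample vector",
                          call. = FALSE)
  }
  if (fs <= 2 * cutoff) {
    stop(sprintf("sampling rate %g Hz puts the %g Hz cutoff at/above Nyquist",
                 fs, cutoff), call. = FALSE)
  }
  detrend <- function(v) {
    t <- seq_along(v)
    as.numeric(stats::.lm.fit(cbind(1, t), v)$residuals)
  }
  # remove the DC level and trend before filtering: the zero-phase filter
  # zero-pads, so a nonzero-mean input would produce large edge transients
  x0 <- detrend(x)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  detrend(as.numeric(signal::filtfilt(bf, x0)))
}

# Topological prominence of a local maximum at index `i`: height above the
# higher of the two deepest valleys separating it from higher terrain.
peak_prominence <- function(x, i) {
  h <- x[i]
  left <- if (i > 1) x[seq_len(i - 1)] else numeric(0)
  right <- if (i < length(x)) x[seq(i + 1, length(x))] else numeric(0)
  base_side <- function(side, from_peak) {
    higher <- which(side > h)
    if (from_peak == "left") {
      lo <- if (length(higher)) max(higher) + 1L else 1L
      if (lo > length(side)) return(h)
      min(side[seq(lo, length(side))])
    } else {
      hi <- if (length(higher)) min(higher) - 1L else length(side)
      if (hi < 1L) return(h)
      min(side[seq_len(hi)])
    }
  }
  lmin <- if (length(left)) base_side(left, "left") else h
  rmin <- if (length(right)) base_side(right, "right") else h
  h - max(lmin, rmin)
}

#' Segment a filtered PPG session into beats
#'
#' Detects systolic peaks with a minimum inter-peak distance of
#' `0.4 * (60 / hr_hint) * fs` samples and a prominence threshold of 0.3
#' times the signal's robust amplitude (2 times the scaled median absolute
#' deviation); beat boundaries (feet) are the signal minima between
#' consecutive peaks, and the partial cycles before the first foot and after
#' the last foot are discarded. Each beat also carries the same index range
#' cut from the raw record, so DC-dependent features stay computable.
#'
#' @param filtered Output of [lowpass_detrend()].
#' @param fs Sampling rate in Hz.
#' @param hr_hint Approximate heart rate in bpm used only for the minimum
#'   peak distance (default 75).
#' @param raw Optional raw (unfiltered) samples of the same length.
#' @return List of [ppg_beat()] objects.
#' @export
segment_beats <- function(filtered, fs, hr_hint = 75, raw = filtered) {
  x <- as.numeric(filtered)
  n <- length(x)
  min_dist <- max(1L, floor(0.4 * (60 / hr_hint) * fs))
  robust_amp <- 2 * stats::mad(x)          # mad() includes the 1.4826 factor
  thr <- 0.3 * robust_amp

  # local maxima; enforce minimum distance first (greedy, taller peak wins)
  # so the O(n)-per-peak prominence check runs on few candidates
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  if (length(cand) > 1) {
    ord <- cand[order(x[cand], decreasing = TRUE)]
    kept <- integer(0)
    for (i in ord) {
      if (!length(kept) || all(abs(kept - i) >= min_dist)) kept <- c(kept, i)
    }
    cand <- sort(kept)
  }
  if (length(cand)) {
    prom <- vapply(cand, function(i) peak_prominence(x, i), numeric(1))
    cand <- cand[prom >= thr]
  }
  if (length(cand) < 3) {
    stop("too few beats: fewer than 3 systolic peaks detected", call. = FALSE)
  }

  feet <- vapply(seq_len(length(cand) - 1L), function(k) {
    lo <- cand[k]; hi <- cand[k + 1L]
    lo + which.min(x[lo:hi]) - 1L
  }, integer(1))

  beats <- list()
  for (k in seq_len(length(feet) - 1L)) {
    idx <- feet[k]:feet[k + 1L]
    if (length(idx) < 0.25 * fs) next  # implausibly short cycle
    beats[[length(beats) + 1L]] <-
      ppg_beat(x[idx], fs, raw_samples = raw[idx])
  }
  if (!length(beats)) {
    stop("too few beats: no complete foot-to-foot cycle", call. = FALSE)
  }
  beats
}

#' Skewness signal-quality index of a beat
#'
#' The Fisher-Pearson moment coefficient `g1 = m3 / m2^1.5` with `mk` the
#' k-th central sample moment (population form, so the downstream 0.1
#' rejection threshold is unambiguous). Clean PPG beats are strongly
#' right-skewed; flat or symmetric beats score near zero.
#'
#' @param beat A [ppg_beat()] or a numeric vector.
#' @return Dimensionless skewness.
#' @export
beat_skewness <- function(beat) {
  x <- if (inherits(beat, "ppg_beat")) beat$samples else as.numeric(beat)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) stop("skewness undefined: zero variance", call. = FALSE)
  mean((x - m)^3) / m2^1.5
}

#' Select the best beat of a session by skewness SQI
#'
#' Picks the beat with maximal skewness; if even that maximum falls below
#' `threshold` the whole session is rejected and contributes no sample.
#' Ties at the maximum resolve to the earliest beat.
#'
#' @param beats Non-empty list of [ppg_beat()]s.
#' @param threshold SQI rejection threshold (default 0.1).
#' @return A list with `beat` (the selected [ppg_beat()], with its `skew`
#'   filled in), `sqi`, and `rejected` (logical).
#' @export
select_best_beat <- function(beats, threshold = 0.1) {
  if (!length(beats)) stop("`beats` must be non-empty", call. = FALSE)
  skews <- vapply(beats, beat_skewness, numeric(1))
  k <- which.max(skews)  # which.max takes the first maximum: earliest beat
  if (skews[k] < threshold) {
    return(list(beat = NULL, sqi = skews[k], rejected = TRUE))
  }
  best <- beats[[k]]
  best$skew <- skews[k]
  list(beat = best, sqi = skews[k], rejected = FALSE)
}
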