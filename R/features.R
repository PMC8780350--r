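#' Named feature sets
#'
#' The three feature combinations studied by the evaluation layer:
#' `set1 = {hr, a02, a25, ri}`, `set2 = {pir, dtr, hr, a02, a25, ri}`,
#' `set3 = {hr, ri}`.
#'
#' @param set_id One of `"set1"`, `"set2"`, `"set3"`.
#' @return Character vector of feature names.
#' @export
feature_set <- function(set_id) {
  switch(match.arg(set_id, c("set1", "set2", "set3")),
    set1 = c("hr", "a02", "a25", "ri"),
    set2 = c("pir", "dtr", "hr", "a02", "a25", "ri"),
    set3 = c("hr", "ri")
  )
}

#' PPG intensity ratio (PIR)
#'
#' Ratio of the raw intensity at the systolic peak to the raw intensity at
#' the beat's foot (its first sample): a surrogate for arterial-diameter
#' change. Computed on the unfiltered, DC-retaining samples by default, since
#' an intensity ratio is meaningless on a detrended zero-mean signal; a
#' minimum-rebased convention is available for sensors with an arbitrary
#' intensity offset.
#'
#' @param beat A [ppg_beat()] with `raw_samples`.
#' @param convention `"absolute"` (raw intensities, default) or `"rebased"`
#'   (both intensities measured above the raw beat minimum).
#' @return Dimensionless ratio (> 0).
#' @export
compute_pir <- function(beat, convention = c("absolute", "rebased")) {
  convention <- match.arg(convention)
  k <- which.max(beat$samples)  # systolic peak located on the filtered beat
  raw <- beat$raw_samples
  if (convention == "rebased") raw <- raw - min(raw)
  foot <- raw[1L]
  if (foot <= 0) stop("PIR undefined: non-positive foot intensity",
                      call. = FALSE)
  raw[k] / foot
}

#' Diastole time ratio (DTR)
#'
#' Fraction of the beat duration after the systolic peak: with the peak at
#' 0-based index `k` of an `N`-sample beat, `DTR = (N - 1 - k) / (N - 1)`.
#'
#' @param beat A [ppg_beat()].
#' @return Value in `[0, 1]`.
#' @export
compute_dtr <- function(beat) {
  n <- length(beat$samples)
  if (n < 2) stop("DTR undefined for a beat of fewer than 2 samples",
                  call. = FALSE)
  k <- which.max(beat$samples)
  (n - k) / (n - 1)
}

#' Locate the downstroke inflection point
#'
#' Finds the inflection landmark on the falling edge after the systolic peak,
#' where the reflected wave props up the decay — the notch-free alternative to
#' identifying a dicrotic notch or diastolic peak. The search is restricted to
#' the window `(k + 0.1 N, N - 0.1 N)` past the peak index `k`; the first
#' derivative is smoothed with a 5-point moving average and the largest
#' interior local maximum of the smoothed derivative is returned. If the
#' derivative has no interior local maximum there, the zero-crossing of the
#' second derivative nearest the window midpoint is used instead.
#'
#' @param beat A filtered [ppg_beat()].
#' @param margin Window margin as a fraction of the beat length.
#' @param smooth Moving-average width (samples) for the derivative.
#' @return Sample index (1-based) of the inflection point.
#' @export
locate_inflection <- function(beat, margin = 0.1, smooth = 5) {
  x <- beat$samples
  n <- length(x)
  k <- which.max(x)
  lo <- max(k + 1L, ceiling(k + margin * n))
  hi <- floor(n - margin * n)
  if (hi - lo < 3) stop("no inflection: search window too short", call. = FALSE)

  d1 <- diff(x)
  d1s <- as.numeric(stats::filter(d1, rep(1 / smooth, smooth), sides = 2))
  win <- lo:(hi - 1L)
  dwin <- d1s[win]
  ok <- which(!is.na(dwin))
  locmax <- ok[ok > 1 & ok < length(dwin)]
  locmax <- locmax[dwin[locmax] >= dwin[locmax - 1] & dwin[locmax] >= dwin[locmax + 1] &
                     (dwin[locmax] > dwin[locmax - 1] | dwin[locmax] > dwin[locmax + 1])]
  if (length(locmax)) {
    return(win[locmax[which.max(dwin[locmax])]])
  }
  # fallback: second-derivative zero-crossing nearest the window midpoint
  d2 <- diff(d1s)
  zc <- which(d2[win[-length(win)]] * d2[win[-length(win)] + 1L] <= 0)
  zc <- zc[!is.na(zc)]
  if (length(zc)) {
    mid <- (length(win)) / 2
    return(win[zc[which.min(abs(zc - mid))]])
  }
  stop("no inflection found on the downstroke", call. = FALSE)
}

#' Reflection-index surrogate (ri)
#'
#' Ratio of the systolic-peak amplitude to the inflection-point amplitude,
#' both rebased to the beat minimum so the ratio is positive and scale-free on
#' detrended signals. Because the peak is the beat maximum, `ri >= 1`; larger
#' reflected waves raise the inflection amplitude and so lower `ri`.
#'
#' @param beat A filtered [ppg_beat()].
#' @param inflection Optional precomputed inflection index.
#' @param ... Passed on to [locate_inflection()].
#' @return Dimensionless ratio `>= 1`.
#' @export
compute_ri <- function(beat, inflection = NULL, ...) {
  x <- beat$samples
  if (is.null(inflection)) inflection <- locate_inflection(beat, ...)
  base <- min(x)
  denom <- x[inflection] - base
  if (denom <= 0) stop("ri undefined: inflection amplitude at the beat minimum",
                       call. = FALSE)
  (max(x) - base) / denom
}

#' Spectral band area of a beat
#'
#' Zero-pads the beat to `8 * fs` samples (0.125 Hz bin spacing), takes the
#' one-sided discrete Fourier magnitude spectrum, and integrates `|S(f)|` by
#' the trapezoidal rule over the half-open band `[f_lo, f_hi)`. The features
#' `a02 = band_area(beat, 0, 2)` and `a25 = band_area(beat, 2, 5)` summarize
#' the beat's low-frequency versus mid-frequency spectral content.
#'
#' @param beat A [ppg_beat()].
#' @param f_lo,f_hi Band edges in Hz, `f_lo < f_hi <= fs / 2`.
#' @return Non-negative spectral area.
#' @export
band_area <- function(beat, f_lo, f_hi) {
  fs <- beat$fs
  if (f_hi <= f_lo || f_hi > fs / 2) {
    stop("invalid band: need f_lo < f_hi <= fs/2", call. = FALSE)
  }
  x <- beat$samples
  nfft <- 8 * round(fs)
  if (length(x) > nfft) nfft <- length(x)
  padded <- c(x, rep(0, nfft - length(x)))
  spec <- abs(stats::fft(padded))[seq_len(nfft %/% 2 + 1L)]
  freq <- (seq_along(spec) - 1) * fs / nfft
  sel <- which(freq >= f_lo & freq < f_hi)
  if (length(sel) < 2) return(0)
  pracma::trapz(freq[sel], spec[sel])
}

#' Extract the feature vector of one session
#'
#' Runs the full single-session pipeline: zero-phase low-pass filtering and
#' detrending, beat segmentation, best-beat selection by skewness SQI, then
#' the per-beat features. Heart rate is copied from the record's device
#' reading, not re-derived from the beat period. Any constituent failure
#' rejects the session with a reason code; a partial vector is never
#' returned.
#'
#' @param record A [ppg_record()].
#' @param set_id Feature set to return (`"set1"`, `"set2"`, `"set3"`, or
#'   `"all"` for all six features).
#' @param sqi_threshold Skewness rejection threshold.
#' @param pir_convention Passed to [compute_pir()].
#' @param hr_hint Heart-rate hint for segmentation; defaults to the record's
#'   device reading.
#' @return A list with `rejected` (logical), `reason` (`NA` or one of
#'   `"too_few_beats"`, `"sqi"`, `"feature"`), `features` (named numeric
#'   vector restricted to the requested set, or `NULL`), and `sqi`.
#' @export
extract_features <- function(record, set_id = "all", sqi_threshold = 0.1,
                             pir_convention = "absolute", hr_hint = NULL) {
  wanted <- if (identical(set_id, "all")) {
    c("hr", "pir", "dtr", "ri", "a02", "a25")
  } else {
    feature_set(set_id)
  }
  if (is.null(hr_hint)) hr_hint <- record$hr_bpm
  reject <- function(reason, sqi = NA_real_) {
    list(rejected = TRUE, reason = reason, features = NULL, sqi = sqi)
  }

  filt <- lowpass_detrend(record)
  beats <- tryCatch(
    segment_beats(filt, record$fs, hr_hint = hr_hint, raw = record$samples),
    error = function(e) NULL)
  if (is.null(beats)) return(reject("too_few_beats"))

  sel <- select_best_beat(beats, threshold = sqi_threshold)
  if (sel$rejected) return(reject("sqi", sqi = sel$sqi))
  beat <- sel$beat

  feats <- tryCatch({
    inf <- locate_inflection(beat)
    c(hr = record$hr_bpm,
      pir = compute_pir(beat, convention = pir_convention),
      dtr = compute_dtr(beat),
      ri = compute_ri(beat, inflection = inf),
      a02 = band_area(beat, 0, 2),
      a25 = band_area(beat, 2, 5))
  }, error = function(e) NULL)
  if (is.null(feats) || any(!is.finite(feats))) return(reject("feature"))

  list(rejected = FALSE, reason = NA_character_,
       features = feats[wanted], sqi = sel$sqi)
}

#' Tidy feature table for a cohort
#'
#' Applies [extract_features()] to every session and returns one row per
#' session with all six features, the reference BP readings, and the
#' rejection status — the table every evaluation routine consumes.
#'
#' @param cohort A `ppg_cohort` from [simulate_cohort()], or a list of
#'   [ppg_record()]s.
#' @param ... Passed to [extract_features()].
#' @return A data frame with columns subject_id, timestamp, hr, pir, dtr,
#'   ri, a02, a25, sbp_ref, dbp_ref, rejected, reject_reason.
#' @export
extract_feature_table <- function(cohort, ...) {
  records <- if (inherits(cohort, "ppg_cohort")) cohort$records else cohort
  rows <- lapply(records, function(r) {
    fx <- extract_features(r, set_id = "all", ...)
    f <- if (fx$rejected) {
      stats::setNames(rep(NA_real_, 6),
                      c("hr", "pir", "dtr", "ri", "a02", "a25"))
    } else {
      fx$features
    }
    data.frame(subject_id = r$subject_id, timestamp = r$timestamp,
               t(f), sbp_ref = r$sbp_ref, dbp_ref = r$dbp_ref,
               rejected = fx$rejected,
               reject_reason = if (fx$rejected) fx$reason else NA_character_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$subject_id, out$timestamp), , drop = FALSE]
}
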