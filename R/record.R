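#' PPG measurement session
#'
#' One raw 30-second (nominal) PPG recording with its paired cuff reference
#' readings. This is the unit every downstream stage consumes.
#'
#' @param samples Numeric intensity vector (arbitrary units).
#' @param fs Sampling rate in Hz (> 0).
#' @param subject_id Subject label.
#' @param timestamp Session time (POSIXct or coercible).
#' @param sbp_ref,dbp_ref Reference cuff SBP/DBP in mmHg (`sbp_ref > dbp_ref`).
#' @param hr_bpm Device heart-rate reading in beats/min.
#' @return An object of class `ppg_record`.
#' @export
ppg_record <- function(samples, fs, subject_id, timestamp,
                       sbp_ref, dbp_ref, hr_bpm) {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a positive scalar", call. = FALSE)
  }
  if (length(samples) < 10 * fs) {
    stop("session too short: need at least 10 s of samples", call. = FALSE)
  }
  if (sbp_ref <= dbp_ref) {
    stop("`sbp_ref` must exceed `dbp_ref`", call. = FALSE)
  }
  structure(list(
    samples = as.numeric(samples), fs = fs,
    subject_id = as.character(subject_id),
    timestamp = as.POSIXct(timestamp, tz = "UTC"),
    sbp_ref = sbp_ref, dbp_ref = dbp_ref, hr_bpm = hr_bpm
  ), class = "ppg_record")
}

#' @export
print.ppg_record <- function(x, ...) {
  cat(sprintf(
    "<ppg_record> subject %s @ %s: %.1f s @ %g Hz, ref %g/%g mmHg, HR %g bpm\n",
    x$subject_id, format(x$timestamp, "%Y-%m-%d %H:%M"),
    length(x$samples) / x$fs, x$fs, x$sbp_ref, x$dbp_ref, x$hr_bpm))
  invisible(x)
}

#' Single segmented cardiac cycle
#'
#' @param samples Filtered intensity vector for one foot-to-foot cycle.
#' @param fs Sampling rate in Hz.
#' @param raw_samples The same index range cut from the unfiltered record
#'   (keeps the DC level needed for the PPG intensity ratio).
#' @param skew Optional precomputed skewness signal-quality index.
#' @return An object of class `ppg_beat`.
#' @export
ppg_beat <- function(samples, fs, raw_samples = samples, skew = NA_real_) {
  if (length(samples) < 0.25 * fs) {
    stop("beat shorter than 250 ms", call. = FALSE)
  }
  structure(list(samples = as.numeric(samples), fs = fs,
                 raw_samples = as.numeric(raw_samples), skew = skew),
            class = "ppg_beat")
}
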