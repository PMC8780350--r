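#' Render one synthetic PPG beat
#'
#' Evaluates the two-Gaussian beat model on a sample grid: baseline plus a
#' systolic bump plus a reflected-wave bump,
#' `baseline + amp_sys * G(t; t_sys, w_sys) + amp_refl * G(t; t_refl, w_refl)`
#' with `G` a unit-peak Gaussian. When `amp_refl > 0` the first derivative of
#' the downstroke has a local maximum between the two bump centers — the
#' inflection landmark the reflection-index surrogate relies on.
#'
#' @param params A [beat_params()] object.
#' @param fs Sampling rate in Hz (> 0).
#' @return Numeric vector of `round(period * fs)` samples.
#' @examples
#' y <- synth_beat(beat_params(amp_refl = 0), fs = 125)
#' which.max(y)  # at the systolic center
#' @export
synth_beat <- function(params, fs) {
  stopifnot(inherits(params, "beat_params"))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a positive scalar", call. = FALSE)
  }
  n <- round(params$period * fs)
  if (n < 2) stop("period too short for the sampling rate", call. = FALSE)
  t <- (seq_len(n) - 1) / fs
  g <- function(center, width) exp(-(t - center)^2 / (2 * width^2))
  params$baseline +
    params$amp_sys * g(params$t_sys_frac * params$period, params$width_sys) +
    params$amp_refl * g(params$t_refl_frac * params$period, params$width_refl)
}

# "Corrupt" beat: a rectified-sine pulse spends most of the cycle near its
# top, so its sample skewness is strongly negative (about -0.5) and the SQI
# stage rejects it, while peak detection still finds a periodic structure.
corrupt_beat_wave <- function(period, fs, amp, baseline, noise_sd) {
  n <- round(period * fs)
  t <- (seq_len(n) - 1) / fs
  carrier <- baseline + amp * abs(sin(pi * t / period))
  z <- stats::rnorm(n, 0, noise_sd)
  carrier + (z - rev(z)) / 2  # antisymmetrized noise keeps the cycle symmetric
}

#' Simulate one PPG measurement session
#'
#' Draws a latent physiological state (heart rate, reflection ratio, pulse
#' timing and amplitude) from the subject's distribution, maps it linearly to
#' the true SBP/DBP (plus slow drift, a circadian sinusoid, and optionally a
#' quadratic heart-rate term), renders `session_seconds` of concatenated
#' two-Gaussian beats at the drawn period, and adds white sensor noise plus a
#' low-frequency baseline-wander sinusoid. With probability
#' `cfg$corrupt_beat_prob` the session's beats are replaced by symmetric
#' low-quality pulses whose skewness falls below the SQI threshold. The
#' recorded reference BP is the true BP plus cuff measurement noise.
#'
#' @param sp A [subject_params()] object.
#' @param day Days since the start of the recording (fractional days carry
#'   the time of day used by the circadian term).
#' @param cfg A [cohort_config()] object.
#' @param seed Integer seed; required so every stochastic call is replayable.
#' @return A [ppg_record()] whose `sbp_ref`/`dbp_ref` are the noisy cuff
#'   references and whose `hr_bpm` is the drawn heart rate. The true
#'   (noise-free) pressures and latent state are attached as the
#'   `"latent"` attribute for diagnostics.
#' @export
synth_session <- function(sp, day, cfg, seed) {
  stopifnot(inherits(sp, "subject_params"), inherits(cfg, "cohort_config"))
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is required: all stochastic generators take an explicit seed",
         call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    clamp <- function(x, lo, hi) min(max(x, lo), hi)
    hr <- clamp(stats::rnorm(1, sp$hr_mean, sp$hr_sd), 40, 180)
    refl <- clamp(stats::rnorm(1, sp$feature_center, sp$feature_spread),
                  0.1, 0.75)
    tsys <- clamp(stats::rnorm(1, sp$t_sys_frac, 0.01), 0.18, 0.42)
    log_amp <- stats::rnorm(1, 0, sp$amp_log_sd)
    amp <- exp(log_amp)

    hour <- (day %% 1) * 24
    circadian <- cfg$circadian_amp * cos(2 * pi * (hour - 16) / 24)
    quad <- if (isTRUE(cfg$nonlinear)) {
      cfg$nonlinear_amp * ((hr - sp$hr_mean) / 10)^2
    } else 0

    sbp_true <- sp$sbp_base + sp$beta_hr * (hr - sp$hr_mean) +
      sp$beta_ri * refl + sp$beta_a * log_amp +
      sp$drift_sbp * day + circadian + quad
    k <- sp$dbp_coef_scale
    dbp_true <- sp$dbp_base + k * (sp$beta_hr * (hr - sp$hr_mean) +
      sp$beta_ri * refl + sp$beta_a * log_amp + quad) +
      sp$drift_dbp * day + k * circadian

    sbp_ref <- sbp_true + stats::rnorm(1, 0, sp$noise_sbp)
    dbp_ref <- dbp_true + stats::rnorm(1, 0, sp$noise_dbp)
    if (dbp_ref >= sbp_ref) dbp_ref <- sbp_ref - 5  # cuff cannot invert

    period <- 60 / hr
    n_target <- round(cfg$session_seconds * cfg$fs)
    n_beats <- ceiling(cfg$session_seconds / period) + 1L
    corrupt <- stats::runif(1) < cfg$corrupt_beat_prob
    beats <- if (corrupt) {
      replicate(n_beats,
                corrupt_beat_wave(period, cfg$fs, amp, sp$baseline, 0.05 * amp),
                simplify = FALSE)
    } else {
      bp <- beat_params(amp_sys = amp, amp_refl = refl * amp,
                        t_sys_frac = tsys, t_refl_frac = clamp(tsys + 0.35, 0.4, 0.95),
                        period = period, baseline = sp$baseline)
      replicate(n_beats, synth_beat(bp, cfg$fs), simplify = FALSE)
    }
    wave <- unlist(beats, use.names = FALSE)[seq_len(n_target)]
    t <- (seq_len(n_target) - 1) / cfg$fs
    wave <- wave +
      cfg$wander_amp * sin(2 * pi * cfg$wander_freq * t + stats::runif(1, 0, 2 * pi))
    if (!corrupt && cfg$ppg_noise_sd > 0) {
      wave <- wave + stats::rnorm(n_target, 0, cfg$ppg_noise_sd)
    }

    timestamp <- as.POSIXct(cfg$start_date, tz = "UTC") + day * 86400
    rec <- ppg_record(wave, cfg$fs, sp$subject_id, timestamp,
                      sbp_ref, dbp_ref, hr)
    attr(rec, "latent") <- list(
      hr = hr, refl = refl, t_sys_frac = tsys, log_amp = log_amp,
      sbp_true = sbp_true, dbp_true = dbp_true, corrupt = corrupt, day = day)
    rec
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a longitudinal PPG/BP cohort
#'
#' Draws per-subject parameters i.i.d. from the population hyper-distributions
#' and simulates each subject's month of sessions at fixed clock times
#' (07:00, 11:00, 15:00, 19:00 for four sessions/day), time-ordered within
#' subject. All randomness flows through `cfg$seed`: identical `(cfg,
#' population)` yield byte-identical cohorts.
#'
#' @param cfg A [cohort_config()] object.
#' @param population Hyper-parameters from [population_defaults()].
#' @return An object of class `ppg_cohort`: a list with `records` (list of
#'   [ppg_record()]s ordered by subject then time), `subjects` (list of the
#'   drawn [subject_params()]), `manifest` (data frame: subject_id, timestamp,
#'   sbp, dbp, hr, day), and the `cfg`/`population` used.
#' @export
simulate_cohort <- function(cfg = cohort_config(),
                            population = population_defaults()) {
  stopifnot(inherits(cfg, "cohort_config"))
  # fixed clock offsets spread over the waking day (07:00 to 19:00)
  slots <- if (cfg$sessions_per_day == 1) {
    7 / 24
  } else {
    seq(7, 19, length.out = cfg$sessions_per_day) / 24
  }
  plan <- withr::with_seed(cfg$seed, {
    ids <- sprintf("S%02d", seq_len(cfg$n_subjects))
    subjects <- lapply(ids, function(id) draw_subject(population, id))
    counts <- if (is.null(cfg$sessions_per_subject)) {
      sample(114:118, cfg$n_subjects, replace = TRUE)
    } else {
      rep(as.integer(cfg$sessions_per_subject), cfg$n_subjects)
    }
    seeds <- sample.int(.Machine$integer.max - 1L, sum(counts))
    list(subjects = subjects, counts = counts, seeds = seeds)
  })

  records <- vector("list", sum(plan$counts))
  k <- 0L
  for (s in seq_len(cfg$n_subjects)) {
    sp <- plan$subjects[[s]]
    for (i in seq_len(plan$counts[s])) {
      day <- (i - 1L) %/% cfg$sessions_per_day +
        slots[(i - 1L) %% cfg$sessions_per_day + 1L]
      k <- k + 1L
      records[[k]] <- synth_session(sp, day, cfg, seed = plan$seeds[k])
    }
  }

  manifest <- data.frame(
    subject_id = vapply(records, function(r) r$subject_id, character(1)),
    timestamp = as.POSIXct(
      vapply(records, function(r) as.numeric(r$timestamp), numeric(1)),
      origin = "1970-01-01", tz = "UTC"),
    sbp = vapply(records, function(r) r$sbp_ref, numeric(1)),
    dbp = vapply(records, function(r) r$dbp_ref, numeric(1)),
    hr = vapply(records, function(r) r$hr_bpm, numeric(1)),
    day = vapply(records, function(r) attr(r, "latent")$day, numeric(1)),
    corrupt = vapply(records, function(r) attr(r, "latent")$corrupt, logical(1))
  )

  structure(list(records = records, subjects = plan$subjects,
                 manifest = manifest, cfg = cfg, population = population),
            class = "ppg_cohort")
}

#' @export
print.ppg_cohort <- function(x, ...) {
  cat(sprintf("<ppg_cohort> %d subjects, %d sessions (%s to %s)\n",
              length(x$subjects), nrow(x$manifest),
              format(min(x$manifest$timestamp), "%Y-%m-%d"),
              format(max(x$manifest$timestamp), "%Y-%m-%d")))
  invisible(x)
}
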