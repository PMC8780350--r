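#' Beat morphology parameters
#'
#' Parametrizes a single synthetic PPG beat as the sum of a systolic Gaussian
#' bump and a reflected-wave Gaussian bump on a DC baseline. The two-bump
#' morphology is the minimal shape that exhibits the landmarks the waveform
#' features rely on (systolic peak, downstroke inflection) without requiring a
#' dicrotic notch or a distinct diastolic peak, which deteriorate with age and
#' hypertension in real PPG.
#'
#' @param amp_sys Systolic bump amplitude (arbitrary intensity units, > 0).
#' @param amp_refl Reflected bump amplitude; must lie in `[0, amp_sys]`.
#' @param t_sys_frac Systolic peak position as a fraction of the period,
#'   in (0, 0.5).
#' @param t_refl_frac Reflected-wave center as a fraction of the period,
#'   in (`t_sys_frac`, 1).
#' @param width_sys,width_refl Gaussian standard deviations in seconds.
#' @param period Cardiac period in seconds (> 0).
#' @param baseline DC offset (arbitrary intensity units).
#' @return An object of class `beat_params`.
#' @examples
#' bp <- beat_params(amp_sys = 1, amp_refl = 0.4, period = 0.8)
#' y <- synth_beat(bp, fs = 125)
#' @export
beat_params <- function(amp_sys = 1, amp_refl = 0.4,
                        t_sys_frac = 0.3, t_refl_frac = 0.65,
                        width_sys = NULL, width_refl = NULL,
                        period = 0.8, baseline = 10) {
  if (!is.numeric(period) || period <= 0) {
    stop("`period` must be positive", call. = FALSE)
  }
  if (is.null(width_sys)) width_sys <- 0.08 * period
  if (is.null(width_refl)) width_refl <- 0.11 * period
  p <- list(
    amp_sys = amp_sys, amp_refl = amp_refl,
    t_sys_frac = t_sys_frac, t_refl_frac = t_refl_frac,
    width_sys = width_sys, width_refl = width_refl,
    period = period, baseline = baseline
  )
  if (amp_sys <= 0) stop("`amp_sys` must be > 0", call. = FALSE)
  if (amp_refl < 0 || amp_refl > amp_sys) {
    stop("`amp_refl` must lie in [0, amp_sys]", call. = FALSE)
  }
  if (!(t_sys_frac > 0 && t_sys_frac < 0.5)) {
    stop("`t_sys_frac` must lie in (0, 0.5)", call. = FALSE)
  }
  if (!(t_refl_frac > t_sys_frac && t_refl_frac < 1)) {
    stop("`t_refl_frac` must lie in (t_sys_frac, 1)", call. = FALSE)
  }
  if (width_sys <= 0 || width_refl <= 0) {
    stop("Gaussian widths must be positive", call. = FALSE)
  }
  structure(p, class = "beat_params")
}

#' Per-subject generative parameters
#'
#' Collects the subject-level quantities that drive the synthetic cohort: BP
#' intercepts, the ground-truth linear coefficients linking the latent
#' physiological state to BP, slow drift slopes (negative values emulate a
#' seasonal decline over a one-month recording), heart-rate distribution,
#' cuff measurement-noise SDs, and the location/scale of the latent reflection
#' state that shapes the waveform.
#'
#' @param subject_id Subject label.
#' @param sbp_base,dbp_base BP intercepts in mmHg (`dbp_base < sbp_base`).
#' @param beta_hr mmHg per bpm linking heart rate to BP.
#' @param beta_ri mmHg per unit of the latent reflection ratio.
#' @param beta_a mmHg per unit log pulse amplitude (0 disables the pathway).
#' @param drift_sbp,drift_dbp mmHg/day slow-trend slopes.
#' @param hr_mean,hr_sd Heart-rate mean/SD in bpm; `hr_mean` in `[40, 120]`.
#' @param noise_sbp,noise_dbp Cuff measurement-noise SDs in mmHg (> 0).
#' @param feature_center,feature_spread Location/scale of the latent
#'   reflection ratio (dimensionless, reflection ratio in `[0, 1]`).
#' @param dbp_coef_scale Factor applied to `beta_hr`/`beta_ri`/`beta_a` for
#'   the DBP map (diastolic pressure responds less than systolic).
#' @param t_sys_frac Subject's typical systolic-peak timing fraction.
#' @param amp_log_sd SD of the per-session log pulse amplitude.
#' @param baseline DC intensity level of the sensor for this subject.
#' @return An object of class `subject_params`.
#' @export
subject_params <- function(subject_id = "S01",
                           sbp_base = 120, dbp_base = 75,
                           beta_hr = 0.5, beta_ri = 8, beta_a = 0,
                           drift_sbp = -0.2, drift_dbp = -0.1,
                           hr_mean = 70, hr_sd = 5,
                           noise_sbp = 3, noise_dbp = 2.5,
                           feature_center = 0.5, feature_spread = 0.08,
                           dbp_coef_scale = 0.5,
                           t_sys_frac = 0.3, amp_log_sd = 0.1,
                           baseline = 10) {
  if (dbp_base >= sbp_base) stop("`dbp_base` must be < `sbp_base`", call. = FALSE)
  if (noise_sbp <= 0 || noise_dbp <= 0) {
    stop("measurement-noise SDs must be > 0", call. = FALSE)
  }
  if (hr_mean < 40 || hr_mean > 120) {
    stop("`hr_mean` must lie in [40, 120] bpm", call. = FALSE)
  }
  structure(list(
    subject_id = subject_id,
    sbp_base = sbp_base, dbp_base = dbp_base,
    beta_hr = beta_hr, beta_ri = beta_ri, beta_a = beta_a,
    drift_sbp = drift_sbp, drift_dbp = drift_dbp,
    hr_mean = hr_mean, hr_sd = hr_sd,
    noise_sbp = noise_sbp, noise_dbp = noise_dbp,
    feature_center = feature_center, feature_spread = feature_spread,
    dbp_coef_scale = dbp_coef_scale,
    t_sys_frac = t_sys_frac, amp_log_sd = amp_log_sd,
    baseline = baseline
  ), class = "subject_params")
}

#' Cohort-level simulation configuration
#'
#' Defaults emulate the study design the package targets: 11 subjects measured
#' roughly four times a day over one month, 114-118 thirty-second PPG sessions
#' each, with a small fraction of sessions corrupted so the signal-quality
#' rejection path is exercised.
#'
#' @param n_subjects Number of subjects (default 11).
#' @param sessions_per_subject Either `NULL` (per-subject count drawn
#'   uniformly from 114-118) or a fixed count.
#' @param sessions_per_day Measurements per day at fixed clock times.
#' @param fs Sampling rate in Hz (>= 50).
#' @param session_seconds Session duration in seconds (>= 10).
#' @param corrupt_beat_prob Probability that a session's beats are replaced by
#'   symmetric low-quality pulses whose skewness falls below the SQI
#'   threshold; in `[0, 1)`.
#' @param circadian_amp Amplitude (mmHg) of the within-day BP sinusoid.
#' @param ppg_noise_sd White sensor-noise SD in intensity units.
#' @param wander_amp,wander_freq Baseline-wander sinusoid amplitude
#'   (intensity units) and frequency (Hz).
#' @param nonlinear Add a quadratic heart-rate term to the true BP map
#'   (off by default; used to study nonlinear regressors).
#' @param nonlinear_amp Size (mmHg) of the quadratic term at one 10-bpm
#'   deviation when `nonlinear` is on.
#' @param start_date First day of the recording (Date or string).
#' @param seed RNG seed for the whole cohort.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 11, sessions_per_subject = NULL,
                          sessions_per_day = 4, fs = 125,
                          session_seconds = 30, corrupt_beat_prob = 0.02,
                          circadian_amp = 3, ppg_noise_sd = 0.01,
                          wander_amp = 0.1, wander_freq = 0.15,
                          nonlinear = FALSE, nonlinear_amp = 3,
                          start_date = "2021-05-15", seed = 1L) {
  if (fs < 50) stop("`fs` must be >= 50 Hz", call. = FALSE)
  if (session_seconds < 10) stop("`session_seconds` must be >= 10", call. = FALSE)
  if (corrupt_beat_prob < 0 || corrupt_beat_prob >= 1) {
    stop("`corrupt_beat_prob` must lie in [0, 1)", call. = FALSE)
  }
  if (n_subjects < 1) stop("`n_subjects` must be >= 1", call. = FALSE)
  structure(list(
    n_subjects = as.integer(n_subjects),
    sessions_per_subject = sessions_per_subject,
    sessions_per_day = as.integer(sessions_per_day),
    fs = fs, session_seconds = session_seconds,
    corrupt_beat_prob = corrupt_beat_prob,
    circadian_amp = circadian_amp,
    ppg_noise_sd = ppg_noise_sd,
    wander_amp = wander_amp, wander_freq = wander_freq,
    nonlinear = nonlinear, nonlinear_amp = nonlinear_amp,
    start_date = as.Date(start_date),
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Population hyper-parameters for subject sampling
#'
#' Means and between-subject SDs from which [simulate_cohort()] draws each
#' subject's [subject_params()]. The defaults describe a normotensive adult
#' cohort: resting SBP around 120 mmHg (between-subject SD 10), DBP around
#' 75 mmHg, heart rate around 70 bpm, a slow decline of a fraction of a mmHg
#' per day, and cuff noise of about 3 mmHg, so that samples from different
#' subjects follow visibly different feature/BP distributions while still
#' partially overlapping in feature space.
#'
#' @param ... Named overrides of any default hyper-parameter.
#' @return A named list of hyper-parameters.
#' @export
population_defaults <- function(...) {
  pop <- list(
    sbp_base_mean = 120, sbp_base_sd = 10,
    dbp_base_mean = 75, dbp_base_sd = 7,
    beta_hr_mean = 0.5, beta_hr_sd = 0.1,
    beta_ri_mean = 8, beta_ri_sd = 2,
    beta_a_mean = 0, beta_a_sd = 0,
    drift_sbp_mean = -0.2, drift_sbp_sd = 0.05,
    drift_dbp_mean = -0.1, drift_dbp_sd = 0.04,
    hr_mean_mean = 70, hr_mean_sd = 8,
    hr_sd_mean = 5, hr_sd_sd = 1,
    noise_sbp = 3, noise_dbp = 2.5,
    feature_center_mean = 0.5, feature_center_sd = 0.1,
    feature_spread = 0.08,
    t_sys_frac_mean = 0.3, t_sys_frac_sd = 0.02,
    baseline_mean = 10, baseline_sd = 1
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(pop))
    if (length(bad)) {
      stop("unknown population hyper-parameter(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    pop[names(dots)] <- dots
  }
  pop
}

# Draw one subject_params from population hyper-parameters (uses the current
# RNG stream; callers are responsible for seeding).
draw_subject <- function(pop, subject_id) {
  clamp <- function(x, lo, hi) min(max(x, lo), hi)
  sbp <- stats::rnorm(1, pop$sbp_base_mean, pop$sbp_base_sd)
  dbp <- stats::rnorm(1, pop$dbp_base_mean, pop$dbp_base_sd)
  if (dbp >= sbp - 20) dbp <- sbp - 20  # keep a plausible pulse pressure
  subject_params(
    subject_id = subject_id,
    sbp_base = sbp, dbp_base = dbp,
    beta_hr = stats::rnorm(1, pop$beta_hr_mean, pop$beta_hr_sd),
    beta_ri = stats::rnorm(1, pop$beta_ri_mean, pop$beta_ri_sd),
    beta_a = stats::rnorm(1, pop$beta_a_mean, pop$beta_a_sd),
    drift_sbp = stats::rnorm(1, pop$drift_sbp_mean, pop$drift_sbp_sd),
    drift_dbp = stats::rnorm(1, pop$drift_dbp_mean, pop$drift_dbp_sd),
    hr_mean = clamp(stats::rnorm(1, pop$hr_mean_mean, pop$hr_mean_sd), 45, 115),
    hr_sd = max(1, stats::rnorm(1, pop$hr_sd_mean, pop$hr_sd_sd)),
    noise_sbp = pop$noise_sbp, noise_dbp = pop$noise_dbp,
    feature_center = clamp(
      stats::rnorm(1, pop$feature_center_mean, pop$feature_center_sd),
      0.15, 0.85),
    feature_spread = pop$feature_spread,
    t_sys_frac = clamp(
      stats::rnorm(1, pop$t_sys_frac_mean, pop$t_sys_frac_sd), 0.2, 0.42),
    baseline = max(2, stats::rnorm(1, pop$baseline_mean, pop$baseline_sd))
  )
}
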