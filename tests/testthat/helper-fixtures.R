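# Shared fixtures, built in code at test time.

# Independent closed-form evaluation of the two-Gaussian beat model: used as
# the oracle against synth_beat and against features computed on its output.
two_gauss_wave <- function(t, amp_sys, amp_refl, t_sys, t_refl,
                           w_sys, w_refl, baseline = 0) {
  baseline +
    amp_sys * exp(-(t - t_sys)^2 / (2 * w_sys^2)) +
    amp_refl * exp(-(t - t_refl)^2 / (2 * w_refl^2))
}

# Noise-free train of k identical beats, rendered through the generator.
make_beat_train <- function(k, hr = 75, fs = 125, amp_refl = 0.4,
                            baseline = 10) {
  bp <- beat_params(amp_sys = 1, amp_refl = amp_refl, period = 60 / hr,
                    baseline = baseline)
  list(wave = rep(synth_beat(bp, fs), k), params = bp, fs = fs)
}

# Quiet subject/config pair for fast noise-controlled sessions.
quiet_cfg <- function(...) {
  args <- list(n_subjects = 2, sessions_per_subject = 20,
               corrupt_beat_prob = 0, circadian_amp = 0,
               ppg_noise_sd = 0, wander_amp = 0, seed = 1)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(cohort_config, args)
}

# Hand-built tidy feature table with a known linear feature->BP map: lets the
# evaluation layer be tested without rendering waveforms.
fake_feature_table <- function(n_subjects = 3, n = 40, seed = 1,
                               sbp_base = NULL, noise = 2) {
  withr::with_seed(seed, {
    if (is.null(sbp_base)) sbp_base <- 115 + 10 * seq_len(n_subjects)
    rows <- lapply(seq_len(n_subjects), function(s) {
      hr <- rnorm(n, 70 + 3 * s, 5)
      ri <- rnorm(n, 2 + 0.2 * s, 0.2)
      a02 <- rnorm(n, 30, 3)
      a25 <- rnorm(n, 20, 2)
      pir <- rnorm(n, 1.1, 0.02)
      dtr <- runif(n, 0.6, 0.8)
      sbp <- sbp_base[s] + 0.5 * (hr - 70) + 4 * ri + rnorm(n, 0, noise)
      dbp <- sbp - 40 + rnorm(n, 0, noise / 2)
      data.frame(subject_id = sprintf("F%02d", s),
                 timestamp = as.POSIXct("2021-05-15", tz = "UTC") +
                   seq_len(n) * 21600,
                 hr = hr, pir = pir, dtr = dtr, ri = ri, a02 = a02, a25 = a25,
                 sbp_ref = sbp, dbp_ref = dbp,
                 rejected = FALSE, reject_reason = NA_character_)
    })
    do.call(rbind, rows)
  })
}
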