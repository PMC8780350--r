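test_that("synth_beat matches the closed-form two-Gaussian model", {
  fs <- 125
  p <- beat_params(amp_sys = 1, amp_refl = 0.4, t_sys_frac = 0.3,
                   t_refl_frac = 0.65, period = 0.8, baseline = 0)
  y <- synth_beat(p, fs)
  expect_length(y, round(0.8 * fs))
  t <- (seq_along(y) - 1) / fs
  oracle <- two_gauss_wave(t, 1, 0.4, 0.3 * 0.8, 0.65 * 0.8,
                           p$width_sys, p$width_refl)
  expect_equal(y, oracle, tolerance = 1e-12)

  # value at the systolic center equals 1 + amp_refl * G(center_sys; refl)
  at_sys <- two_gauss_wave(0.3 * 0.8, 1, 0.4, 0.3 * 0.8, 0.65 * 0.8,
                           p$width_sys, p$width_refl)
  expect_equal(at_sys,
               1 + 0.4 * exp(-(0.3 * 0.8 - 0.65 * 0.8)^2 /
                               (2 * p$width_refl^2)))
})

test_that("single-bump degenerate case peaks at the systolic center", {
  fs <- 125
  p <- beat_params(amp_refl = 0, t_sys_frac = 0.3, period = 0.8,
                   baseline = 2)
  y <- synth_beat(p, fs)
  expect_equal(which.max(y), round(0.3 * 0.8 * fs) + 1L)
  # detrended waveform is homogeneous in the amplitudes
  p2 <- beat_params(amp_sys = 2, amp_refl = 0.8, period = 0.8, baseline = 2)
  p1 <- beat_params(amp_sys = 1, amp_refl = 0.4, period = 0.8, baseline = 2)
  expect_equal(synth_beat(p2, fs) - 2, 2 * (synth_beat(p1, fs) - 2),
               tolerance = 1e-12)
})

test_that("invalid beat parameters and sampling rates are refused", {
  expect_error(beat_params(period = -1), "period")
  expect_error(beat_params(amp_sys = 0), "amp_sys")
  expect_error(beat_params(amp_refl = 2, amp_sys = 1), "amp_refl")
  expect_error(beat_params(t_sys_frac = 0.6), "t_sys_frac")
  expect_error(synth_beat(beat_params(), fs = -5), "fs")
})

test_that("synth_session is seed-deterministic and requires a seed", {
  sp <- subject_params()
  cfg <- quiet_cfg()
  expect_error(synth_session(sp, day = 1, cfg), "seed")
  a <- synth_session(sp, day = 1.3, cfg, seed = 99)
  b <- synth_session(sp, day = 1.3, cfg, seed = 99)
  expect_identical(a$samples, b$samples)
  expect_identical(a$sbp_ref, b$sbp_ref)
  d <- synth_session(sp, day = 1.3, cfg, seed = 100)
  expect_false(identical(a$samples, d$samples))
})

test_that("noise-free limit: reference BP equals the linear latent map", {
  sp <- subject_params(noise_sbp = 1e-12, noise_dbp = 1e-12,
                       drift_sbp = 0, drift_dbp = 0)
  cfg <- quiet_cfg()
  rec <- synth_session(sp, day = 3.5, cfg, seed = 7)
  l <- attr(rec, "latent")
  expected_sbp <- sp$sbp_base + sp$beta_hr * (l$hr - sp$hr_mean) +
    sp$beta_ri * l$refl
  expect_equal(rec$sbp_ref, expected_sbp, tolerance = 1e-6)
  expected_dbp <- sp$dbp_base + sp$dbp_coef_scale *
    (sp$beta_hr * (l$hr - sp$hr_mean) + sp$beta_ri * l$refl)
  expect_equal(rec$dbp_ref, expected_dbp, tolerance = 1e-6)
})

test_that("cohort has the study shape: subjects, session counts, ordering", {
  cfg <- cohort_config(n_subjects = 3, fs = 50, session_seconds = 10,
                       seed = 21)
  co <- simulate_cohort(cfg)
  expect_s3_class(co, "ppg_cohort")
  counts <- table(co$manifest$subject_id)
  expect_length(counts, 3)
  expect_true(all(counts >= 114 & counts <= 118))
  # ~30 days of recording, ordered in time within subject
  for (s in names(counts)) {
    ts <- co$manifest$timestamp[co$manifest$subject_id == s]
    expect_false(is.unsorted(ts))
    expect_gt(as.numeric(difftime(max(ts), min(ts), units = "days")), 26)
  }
  # byte-for-byte determinism of the downstream table
  co2 <- simulate_cohort(cfg)
  expect_identical(co$manifest, co2$manifest)
  expect_identical(co$records[[5]]$samples, co2$records[[5]]$samples)
})

test_that("noise-free ri is strictly monotone in the reflection ratio", {
  fs <- 125
  ris <- vapply(seq(0.2, 0.8, by = 0.1), function(refl) {
    y <- synth_beat(beat_params(amp_sys = 1, amp_refl = refl,
                                period = 0.8, baseline = 0), fs)
    compute_ri(ppg_beat(y, fs))
  }, numeric(1))
  expect_true(all(diff(ris) < 0))
})

test_that("drift slope is recovered by OLS within 3 standard errors", {
  co <- simulate_cohort(cohort_config(n_subjects = 2, fs = 50,
                                      session_seconds = 10, seed = 31))
  for (i in seq_along(co$subjects)) {
    sp <- co$subjects[[i]]
    d <- co$manifest[co$manifest$subject_id == sp$subject_id, ]
    fit <- summary(stats::lm(sbp ~ day, data = d))$coefficients
    expect_lt(abs(fit["day", "Estimate"] - sp$drift_sbp),
              3 * fit["day", "Std. Error"])
  }
})

test_that("between-subject SBP spread matches the population spread", {
  pop <- population_defaults()
  sds <- vapply(1:20, function(r) {
    co <- simulate_cohort(cohort_config(n_subjects = 11, fs = 50,
                                        session_seconds = 10,
                                        sessions_per_subject = 16,
                                        sessions_per_day = 4,
                                        seed = 400 + r), pop)
    stats::sd(tapply(co$manifest$sbp, co$manifest$subject_id, mean))
  }, numeric(1))
  expect_lt(abs(mean(sds) - pop$sbp_base_sd) / pop$sbp_base_sd, 0.25)
})

test_that("zero between-subject variance collapses intra/inter similarity", {
  pop0 <- population_defaults(
    sbp_base_sd = 0, dbp_base_sd = 0, beta_hr_sd = 0, beta_ri_sd = 0,
    drift_sbp_sd = 0, drift_dbp_sd = 0, hr_mean_sd = 0, hr_sd_sd = 0,
    feature_center_sd = 0, t_sys_frac_sd = 0, baseline_sd = 0)
  co <- simulate_cohort(cohort_config(n_subjects = 4,
                                      sessions_per_subject = 40,
                                      seed = 17), pop0)
  ft <- extract_feature_table(co)
  sim <- similarity_histograms(ft, set_id = "set1", seed = 5)
  ks <- suppressWarnings(stats::ks.test(sim$intra, sim$inter)$statistic)
  expect_lt(unname(ks), 0.12)
  # ... while the default heterogeneous population separates them
  co2 <- simulate_cohort(cohort_config(n_subjects = 4,
                                       sessions_per_subject = 40,
                                       seed = 17))
  sim2 <- similarity_histograms(extract_feature_table(co2), seed = 5)
  expect_gt(sim2$median_intra, sim2$median_inter)
})
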