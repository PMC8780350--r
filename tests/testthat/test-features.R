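test_that("PIR is the raw peak-to-foot intensity ratio", {
  b <- ppg_beat(c(0, 1, 2, 1, 0.2, 0), fs = 20,
                raw_samples = c(1, 2, 2.0, 1.5, 1.2, 1.1))
  # filtered argmax at index 3 -> raw[3] / raw[1]
  expect_equal(compute_pir(b), 2.0 / 1)
  # constant raw beat -> 1
  bc <- ppg_beat(c(0, 1, 0, 1, 0, 1), fs = 20, raw_samples = rep(3, 6))
  expect_equal(compute_pir(bc), 1)
  # non-positive foot -> error; rebased convention rebases to the raw minimum
  bneg <- ppg_beat(c(0, 1, 0, 1, 0, 1), fs = 20,
                   raw_samples = c(0, 1, 2, 1, 1, 1))
  expect_error(compute_pir(bneg), "foot")
  br <- ppg_beat(c(0, 2, 0, 1, 0, 1), fs = 20,
                 raw_samples = c(5, 7, 6, 5, 4, 4.5))
  expect_equal(compute_pir(br, convention = "rebased"), (7 - 4) / (5 - 4))
  expect_error(compute_pir(bneg, convention = "rebased"), "foot")
})

test_that("PIR on a generated beat matches the closed-form waveform", {
  fs <- 125
  p <- beat_params(amp_sys = 1, amp_refl = 0, t_sys_frac = 0.3,
                   period = 0.8, baseline = 10)
  raw <- synth_beat(p, fs)
  beat <- ppg_beat(raw - mean(raw), fs, raw_samples = raw)
  t <- (seq_along(raw) - 1) / fs
  oracle <- two_gauss_wave(t, 1, 0, 0.24, 0.52, p$width_sys, p$width_refl,
                           baseline = 10)
  k <- which.max(oracle)
  expect_equal(compute_pir(beat), oracle[k] / oracle[1], tolerance = 1e-12)
})

test_that("DTR follows the peak-position convention", {
  expect_equal(compute_dtr(ppg_beat(c(5, 4, 3, 2, 1), fs = 4)), 1)
  expect_equal(compute_dtr(ppg_beat(c(1, 2, 3, 4, 5), fs = 4)), 0)
  x <- c(seq(0, 1, length.out = 31), seq(1, 0, length.out = 71)[-1])
  expect_length(x, 101)
  expect_equal(compute_dtr(ppg_beat(x, fs = 100)), 0.70)
  expect_error(compute_dtr(ppg_beat(1, fs = 1)), "fewer than 2|250 ms")
})

test_that("inflection lands between the bump centers, matching the analytic
           derivative maximum", {
  fs <- 500  # fine grid so the oracle comparison is sharp
  p <- beat_params(amp_sys = 1, amp_refl = 0.4, t_sys_frac = 0.3,
                   t_refl_frac = 0.65, period = 0.8, baseline = 0)
  y <- synth_beat(p, fs)
  beat <- ppg_beat(y, fs)
  idx <- locate_inflection(beat)
  c_sys <- round(0.3 * 0.8 * fs) + 1
  c_refl <- round(0.65 * 0.8 * fs) + 1
  expect_gt(idx, c_sys)
  expect_lt(idx, c_refl)
  # brute-force argmax of the analytic first derivative on the window
  t <- (seq_along(y) - 1) / fs
  g <- function(tt, c, w) exp(-(tt - c)^2 / (2 * w^2))
  d1 <- -(t - 0.24) / p$width_sys^2 * g(t, 0.24, p$width_sys) -
    0.4 * (t - 0.52) / p$width_refl^2 * g(t, 0.52, p$width_refl)
  n <- length(y)
  win <- ceiling(which.max(y) + 0.1 * n):floor(n - 0.1 * n)
  oracle_idx <- win[which.max(d1[win])]
  expect_lt(abs(idx - oracle_idx), 0.01 * fs)  # within 10 ms
})

test_that("second-derivative fallback fires on a reflection-free downstroke", {
  fs <- 125
  p <- beat_params(amp_sys = 1, amp_refl = 0, t_sys_frac = 0.3,
                   width_sys = 0.15 * 0.8, period = 0.8, baseline = 0)
  beat <- ppg_beat(synth_beat(p, fs), fs)
  idx <- locate_inflection(beat)
  n <- length(beat$samples)
  k <- which.max(beat$samples)
  expect_gte(idx, ceiling(k + 0.1 * n))
  expect_lte(idx, floor(n - 0.1 * n))
  # amplitude scaling does not move the landmark
  beat3 <- ppg_beat(3 * beat$samples, fs)
  expect_equal(locate_inflection(beat3), idx)
})

test_that("ri is the rebased peak-to-inflection ratio, >= 1", {
  x <- c(0, 0.2, 1, 0.8, 0.5, 0.4, 0.3, 0.1, 0)
  b <- ppg_beat(x, fs = 30)
  expect_equal(compute_ri(b, inflection = 5), 1 / 0.5)
  expect_equal(compute_ri(b, inflection = 3), 1)  # inflection at the peak
  expect_error(compute_ri(b, inflection = 9), "minimum")
})

test_that("band areas separate low and mid frequency content", {
  fs <- 125
  # tapered segments, like natural foot-to-foot beats: an abrupt cut would
  # smear magnitude leakage across bands
  t <- seq(0, 2, by = 1 / fs)
  w <- 0.5 * (1 - cos(pi * t))
  b1 <- ppg_beat(w * sin(2 * pi * 1 * t), fs)
  expect_lt(band_area(b1, 2, 5) / band_area(b1, 0, 2), 0.02)
  b3 <- ppg_beat(w * sin(2 * pi * 3 * t), fs)
  expect_lt(band_area(b3, 0, 2) / band_area(b3, 2, 5), 0.02)
  b13 <- ppg_beat(w * (sin(2 * pi * 1 * t) + sin(2 * pi * 3 * t)), fs)
  a02 <- band_area(b13, 0, 2)
  a25 <- band_area(b13, 2, 5)
  expect_lt(abs(a02 - a25) / a02, 0.05)
  expect_error(band_area(b1, 5, 2), "invalid band")
  expect_error(band_area(b1, 0, 100), "invalid band")
})

test_that("extract_features returns finite vectors, set restriction, and
           rejection reasons", {
  sp <- subject_params()
  cfg <- quiet_cfg(ppg_noise_sd = 0.01, wander_amp = 0.1)
  rec <- synth_session(sp, day = 2.5, cfg, seed = 11)
  fx <- extract_features(rec)
  expect_false(fx$rejected)
  expect_named(fx$features, c("hr", "pir", "dtr", "ri", "a02", "a25"))
  expect_true(all(is.finite(fx$features)))
  expect_gt(fx$features["dtr"], 0)
  expect_lt(fx$features["dtr"], 1)
  expect_gt(fx$features["ri"], 1)
  expect_gt(fx$features["pir"], 0)
  expect_equal(unname(fx$features["hr"]), rec$hr_bpm)

  fx3 <- extract_features(rec, set_id = "set3")
  expect_named(fx3$features, c("hr", "ri"))

  cfg_bad <- cohort_config(n_subjects = 2, sessions_per_subject = 20,
                           corrupt_beat_prob = 0.999, seed = 2)
  fx_bad <- extract_features(synth_session(sp, day = 2.5, cfg_bad, seed = 12))
  expect_true(fx_bad$rejected)
  expect_equal(fx_bad$reason, "sqi")
  expect_null(fx_bad$features)
})

test_that("feature scale behavior: dtr/ri/pir invariant, band areas linear", {
  sp <- subject_params()
  rec <- synth_session(sp, day = 2.5, quiet_cfg(), seed = 11)
  rec3 <- rec
  rec3$samples <- rec$samples * 3  # gain change scales baseline too
  f1 <- extract_features(rec)$features
  f3 <- extract_features(rec3)$features
  expect_equal(f3["dtr"], f1["dtr"], tolerance = 1e-9)
  expect_equal(f3["ri"], f1["ri"], tolerance = 1e-9)
  expect_equal(f3["pir"], f1["pir"], tolerance = 1e-9)
  expect_equal(unname(f3[c("a02", "a25")]), unname(3 * f1[c("a02", "a25")]),
               tolerance = 1e-9)
})

test_that("feature invariants hold across a simulated sweep", {
  co <- simulate_cohort(cohort_config(n_subjects = 4,
                                      sessions_per_subject = 30, seed = 8))
  ft <- extract_feature_table(co)
  ok <- !ft$rejected
  expect_gt(sum(ok), 100)
  expect_true(all(ft$dtr[ok] >= 0 & ft$dtr[ok] <= 1))
  expect_true(all(ft$ri[ok] >= 1))
  expect_true(all(ft$a02[ok] >= 0 & ft$a25[ok] >= 0))
  expect_true(all(ft$pir[ok] > 0))
})
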