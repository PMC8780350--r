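test_that("constant input filters and detrends to zero", {
  y <- lowpass_detrend(rep(5, 1000), fs = 125)
  expect_lt(max(abs(y)), 1e-8)
})

test_that("sinusoid attenuation follows the squared Butterworth magnitude", {
  fs <- 125
  t <- seq(0, 30, by = 1 / fs)
  keep <- seq(2 * fs, length(t) - 2 * fs)  # trim filter edge transients
  for (f in c(1, 2, 5, 10)) {
    x <- sin(2 * pi * f * t)
    y <- lowpass_detrend(x, fs = fs)
    measured <- sqrt(mean(y[keep]^2)) / sqrt(mean(x[keep]^2))
    analytic <- 1 / (1 + (f / 10)^12)  # two zero-phase passes
    expect_lt(abs(measured - analytic), 0.01)
  }
  # 20 Hz: beyond cutoff, effectively zero
  x <- sin(2 * pi * 20 * t)
  y <- lowpass_detrend(x, fs = fs)
  expect_lt(sqrt(mean(y[keep]^2)) / sqrt(mean(x[keep]^2)), 1e-3)
})

test_that("filtering is zero-phase for band-limited input", {
  fs <- 125
  t <- seq(0, 20, by = 1 / fs)
  x <- sin(2 * pi * 2 * t) + 0.5 * sin(2 * pi * 4.5 * t)
  y <- lowpass_detrend(x, fs = fs)
  keep <- seq(2 * fs, length(t) - 2 * fs)
  cc <- stats::ccf(y[keep], x[keep], lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("a too-low sampling rate is refused", {
  expect_error(lowpass_detrend(rnorm(100), fs = 20), "Nyquist")
})

test_that("beat trains segment into k-2 complete foot-to-foot cycles", {
  for (hr in c(50, 75, 100)) {
    tr <- make_beat_train(10, hr = hr)
    filt <- lowpass_detrend(tr$wave, fs = tr$fs)
    beats <- segment_beats(filt, tr$fs, hr_hint = hr, raw = tr$wave)
    expect_length(beats, 8)  # edge partial cycles dropped
    period_samples <- round(60 / hr * tr$fs)
    lens <- vapply(beats, function(b) length(b$samples), numeric(1))
    expect_true(all(abs(lens - period_samples) <= 2))
  }
})

test_that("segmentation is amplitude-invariant and rejects white noise", {
  tr <- make_beat_train(12)
  filt <- lowpass_detrend(tr$wave, fs = tr$fs)
  b1 <- segment_beats(filt, tr$fs, raw = tr$wave)
  b2 <- segment_beats(3 * filt, tr$fs, raw = tr$wave)
  expect_equal(lapply(b1, function(b) length(b$samples)),
               lapply(b2, function(b) length(b$samples)))
  expect_equal(b1[[1]]$samples * 3, b2[[1]]$samples)

  # white noise has no periodic structure: either no usable peaks, or the
  # "beats" it yields are wildly irregular compared with a clean train
  noise <- withr::with_seed(4, rnorm(30 * 125))
  res <- tryCatch(
    segment_beats(lowpass_detrend(noise, fs = 125), 125, raw = noise),
    error = function(e) e)
  if (inherits(res, "error")) {
    expect_match(conditionMessage(res), "too few beats")
  } else {
    lens <- vapply(res, function(b) length(b$samples), numeric(1))
    expect_gt(stats::sd(lens) / mean(lens), 0.15)
  }
  clean_lens <- vapply(b1, function(b) length(b$samples), numeric(1))
  expect_lt(stats::sd(clean_lens) / mean(clean_lens), 0.02)
})

test_that("skewness is the population moment coefficient g1", {
  # brute-force moment oracle
  x <- c(0, 0, 0, 1)
  m2 <- mean((x - mean(x))^2)
  m3 <- mean((x - mean(x))^3)
  expect_equal(beat_skewness(x), m3 / m2^1.5)
  # symmetric data scores zero; location/scale invariant
  sym <- c(1, 2, 3, 4, 4, 3, 2, 1)
  expect_lt(abs(beat_skewness(sym)), 1e-12)
  y <- withr::with_seed(1, rexp(100))
  expect_equal(beat_skewness(y), beat_skewness(y + 10), tolerance = 1e-9)
  expect_equal(beat_skewness(y), beat_skewness(y * 3), tolerance = 1e-9)
  expect_error(beat_skewness(rep(2, 50)), "zero variance")
  # agrees with the independent implementation when available
  if (requireNamespace("e1071", quietly = TRUE)) {
    expect_equal(beat_skewness(y), e1071::skewness(y, type = 1),
                 tolerance = 1e-12)
  }
})

test_that("best-beat selection maximizes skewness and applies the threshold", {
  mk <- function(skew_target) {
    # beats engineered to a given sign/size of skewness via exponent shaping
    t <- seq(0, 1, length.out = 60)
    ppg_beat(exp(-(t - 0.3)^2 / (2 * (0.05 + 0.2 * (1 - skew_target))^2)),
             fs = 125)
  }
  b1 <- mk(0.2); b2 <- mk(0.9); b3 <- mk(0.5)
  skews <- vapply(list(b1, b2, b3), beat_skewness, numeric(1))
  sel <- select_best_beat(list(b1, b2, b3))
  expect_false(sel$rejected)
  expect_equal(sel$sqi, max(skews))
  expect_equal(sel$beat$samples, list(b1, b2, b3)[[which.max(skews)]]$samples)

  # all below threshold -> session rejected
  broad <- ppg_beat(abs(sin(pi * seq(0, 1, length.out = 80))), fs = 125)
  expect_lt(beat_skewness(broad), 0.1)
  expect_true(select_best_beat(list(broad, broad))$rejected)
  # tie resolves to the earliest beat
  tie <- select_best_beat(list(b2, b2))
  expect_equal(tie$beat$samples, b2$samples)
  expect_error(select_best_beat(list()), "non-empty")
})

test_that("SQI pipeline rejects corrupt sessions and passes clean ones", {
  sp <- subject_params()
  cfg_corrupt <- cohort_config(n_subjects = 2, sessions_per_subject = 20,
                               corrupt_beat_prob = 0.999, seed = 3)
  cfg_clean <- cohort_config(n_subjects = 2, sessions_per_subject = 20,
                             corrupt_beat_prob = 0, seed = 3)
  pop <- population_defaults()
  for (i in 1:100) {
    spi <- withr::with_seed(i, ppgbp:::draw_subject(pop, "S"))
    day <- (i %% 29) + 0.4
    fx_c <- extract_features(synth_session(spi, day, cfg_corrupt,
                                           seed = 5000 + i))
    expect_true(fx_c$rejected)
    expect_equal(fx_c$reason, "sqi")
    fx_0 <- extract_features(synth_session(spi, day, cfg_clean,
                                           seed = 6000 + i))
    expect_false(fx_0$rejected)
  }
})
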