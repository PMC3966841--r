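# ERG decay fitting, prediction intervals, treatment-window arithmetic.

test_that("fit_decay recovers a noise-free line exactly", {
  p <- erg_cohort_params(scatter_sd = 0, noise_floor = 0, seed = 1)
  fit <- suppressWarnings(fit_decay(gen_erg_cohort(p)))  # perfect fit
  expect_equal(fit$slope, p$slope_log, tolerance = 1e-9)
  expect_equal(fit$intercept, p$intercept_log, tolerance = 1e-9)
  expect_lt(fit$residual_sd, 1e-9)
  # two-point oracle: slope = log10(22/139)/52 = -0.0153960 (printed
  # endpoint means at P31 and P83)
  two <- data.frame(age_days = c(31, 31, 83, 83),
                    amplitude_uV = c(139, 139, 22, 22))
  f2 <- suppressWarnings(fit_decay(two))
  expect_equal(f2$slope, log10(22 / 139) / 52, tolerance = 1e-12)
  expect_equal(f2$slope, -0.015396, tolerance = 1e-6)
  # constant amplitudes: slope 0
  cst <- data.frame(age_days = c(30, 50, 70), amplitude_uV = rep(80, 3))
  expect_equal(suppressWarnings(fit_decay(cst))$slope, 0, tolerance = 1e-12)
})

test_that("noise-floor policies drop or censor sub-floor records", {
  rec <- data.frame(age_days = c(30, 40, 50, 60, 90),
                    amplitude_uV = c(100, 60, 40, 20, 3))
  fd <- fit_decay(rec, floor_policy = "drop", noise_floor = 5)
  expect_equal(fd$n, 4L)
  fc <- fit_decay(rec, floor_policy = "censor", noise_floor = 5)
  expect_equal(fc$n, 5L)
  allfloor <- data.frame(age_days = c(30, 40, 50), amplitude_uV = c(1, 2, 3))
  expect_error(fit_decay(allfloor, noise_floor = 5), "noise floor")
  mixed <- data.frame(age_days = 1:6, amplitude_uV = 10:15,
                      stimulus = rep(c("UV", "M"), 3))
  expect_error(fit_decay(mixed), "single stimulus")
})

test_that("percent_per_day converts the log slope to a daily loss rate", {
  # closed form: 100 * (1 - 10^(-0.0153966)) = 3.483 (hand-computed)
  expect_equal(percent_per_day(decay_fit(-0.0153966, 2.62)), 3.483,
               tolerance = 2e-3)
  expect_equal(percent_per_day(decay_fit(0, 2)), 0)
  expect_equal(percent_per_day(decay_fit(-1, 2)), 90)
  expect_error(percent_per_day(decay_fit(0.1, 2)), "<= 0")
  # round trip through the generator: data generated at rate r%/day
  r <- 4
  slope <- log10(1 - r / 100)
  p <- erg_cohort_params(slope_log = slope, scatter_sd = 0, noise_floor = 0,
                         seed = 1)
  expect_equal(percent_per_day(suppressWarnings(fit_decay(gen_erg_cohort(p)))), r,
               tolerance = 1e-9)
})

test_that("predict_amplitude evaluates the fit with its prediction interval", {
  # 1.4 log uV with halfwidth 0.4: interval 10^{1.0, 1.8}, mean 25.1 uV
  fit <- decay_fit(slope = 0, intercept = 1.4, pi95_halfwidth = 0.4, n = 95)
  pr <- predict_amplitude(fit, 65)
  expect_equal(pr$mean_uV, 25.11886, tolerance = 1e-5)
  expect_equal(pr$pi_low_uV, 10, tolerance = 1e-9)
  expect_equal(pr$pi_high_uV, 63.09573, tolerance = 1e-5)
  # degenerate halfwidth and age-independence at slope 0
  fit0 <- decay_fit(slope = 0, intercept = 1.4, pi95_halfwidth = 0, n = 95)
  pr0 <- predict_amplitude(fit0, 40)
  expect_equal(pr0$pi_low_uV, pr0$mean_uV)
  expect_equal(predict_amplitude(fit0, 80)$mean_uV, pr0$mean_uV)
  # monotone decreasing in age when slope < 0
  fd <- decay_fit(slope = -0.0154, intercept = 2.62, n = 95)
  ages <- seq(31, 83, by = 2)
  preds <- vapply(ages, function(a) predict_amplitude(fd, a)$mean_uV,
                  numeric(1))
  expect_true(all(diff(preds) < 0))
  # extrapolation warning outside +-20% of the fitted range
  fr <- decay_fit(slope = -0.01, intercept = 2, n = 10, age_range = c(31, 83))
  expect_warning(predict_amplitude(fr, 200), "extrapolation")
})

test_that("exact prediction interval widens away from the design centre", {
  p <- erg_cohort_params(scatter_sd = 0.2, n_per_age = 5, seed = 3)
  fit <- fit_decay(gen_erg_cohort(p), noise_floor = 5)
  hw_centre <- predict_amplitude(fit, fit$age_center, interval = "exact")$log_halfwidth
  hw_edge <- predict_amplitude(fit, 31, interval = "exact")$log_halfwidth
  expect_equal(hw_centre, fit$pi95_halfwidth, tolerance = 1e-12)
  expect_gt(hw_edge, hw_centre)
})

test_that("plan_window derives thresholds from the asymmetry bound", {
  # anchor the fit so the predicted log-mean at P65 is exactly 1.4
  fit <- decay_fit(slope = (1.4 - 1.9) / (65 - 37.5),
                   intercept = 1.9 + (1.9 - 1.4) / (65 - 37.5) * 37.5,
                   n = 95)
  w <- plan_window(fit, inject_age = 37, assess_delay = 28, asym_log = 0.3)
  expect_equal(w$assess_age, 65)
  expect_equal(w$expected_untreated_mean, 25.11886, tolerance = 1e-5)
  expect_equal(w$efficacy_threshold, 10^1.7, tolerance = 1e-9)
  expect_equal(w$toxicity_threshold, 10^1.1, tolerance = 1e-9)
  # ordering invariant
  expect_true(w$toxicity_threshold < w$expected_untreated_mean)
  expect_true(w$expected_untreated_mean < w$efficacy_threshold)
  # log-symmetry: efficacy * toxicity = mean^2
  expect_equal(w$efficacy_threshold * w$toxicity_threshold,
               w$expected_untreated_mean^2, tolerance = 1e-9)
  # asym -> 0 collapses the thresholds onto the mean
  w0 <- plan_window(fit, 37, 28, asym_log = 1e-9)
  expect_equal(w0$efficacy_threshold, w0$expected_untreated_mean,
               tolerance = 1e-6)
  # doubling asym squares the threshold ratio
  w2 <- plan_window(fit, 37, 28, asym_log = 0.6)
  r1 <- w$efficacy_threshold / w$toxicity_threshold
  expect_equal(w2$efficacy_threshold / w2$toxicity_threshold, r1^2,
               tolerance = 1e-9)
  # below-floor flag when the window is too late
  expect_warning(wl <- plan_window(fit, 150, 28, 0.3, noise_floor = 5),
                 "too late")
  expect_true(wl$below_floor)
})

test_that("classify_interocular orders outcomes around the window", {
  fit <- decay_fit(slope = 0, intercept = 1.4, n = 95)
  w <- plan_window(fit, 37, 28, 0.3)
  expect_identical(classify_interocular(60, 25, w), "efficacy")
  expect_identical(classify_interocular(25.1, 25, w), "within_asymmetry")
  expect_identical(classify_interocular(10, 25, w), "toxicity")
  expect_error(classify_interocular(-1, 25, w), "> 0")
})

test_that("slope 95% CI covers the generating slope in >= 90% of cohorts", {
  true_slope <- (log10(22) - log10(139)) / 52
  covered <- 0L
  n_runs <- 200L
  for (s in seq_len(n_runs)) {
    p <- erg_cohort_params(scatter_sd = 0.2, n_per_age = 5,
                           ages = round(seq(31, 83, length.out = 19)),
                           seed = 5000 + s)
    fit <- fit_decay(gen_erg_cohort(p), noise_floor = 5)
    se <- fit$residual_sd / sqrt(fit$sxx)
    ci <- fit$slope + c(-1, 1) * stats::qt(0.975, fit$n - 2) * se
    if (true_slope >= ci[1] && true_slope <= ci[2]) covered <- covered + 1L
  }
  expect_gte(covered, 0.9 * n_runs)
})
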