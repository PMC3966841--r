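# Exponential (log-linear) ERG amplitude decay modelling and the
# treatment-window calculator based on interocular asymmetry bounds.

#' Construct a log-linear amplitude decay fit
#'
#' Usually produced by [fit_decay()]; the constructor also allows a fit to
#' be specified directly from published parameters (e.g. a printed slope and
#' prediction-interval half-width) for window planning.
#'
#' @param slope log10 uV per day.
#' @param intercept log10 uV at age 0.
#' @param residual_sd residual SD, log10 uV.
#' @param pi95_halfwidth 95% prediction-interval half-width at the design
#'   centre, log10 uV.
#' @param n number of records fitted.
#' @param stimulus `"UV"` or `"M"`.
#' @param age_range fitted age range (days), used for extrapolation warnings.
#' @param age_center,sxx design centre and sum of squares of ages, for the
#'   exact (age-dependent) prediction interval; optional.
#' @return object of class `decay_fit`.
#' @export
decay_fit <- function(slope, intercept, residual_sd = 0, pi95_halfwidth = 0,
                      n = 3L, stimulus = "UV", age_range = NULL,
                      age_center = NULL, sxx = NULL) {
  check_that(pi95_halfwidth >= 0 && residual_sd >= 0,
             "residual_sd and pi95_halfwidth must be >= 0")
  check_that(n >= 3L, "n must be >= 3")
  structure(list(slope = slope, intercept = intercept,
                 residual_sd = residual_sd,
                 pi95_halfwidth = pi95_halfwidth, n = as.integer(n),
                 stimulus = stimulus, age_range = age_range,
                 age_center = age_center, sxx = sxx),
            class = "decay_fit")
}

#' Fit the log-linear ERG amplitude decay
#'
#' Ordinary least squares of log10 amplitude on age.  Records at or below
#' the noise floor are dropped (default) or censored at the floor before
#' log-transforming, per `floor_policy`.  The 95% prediction-interval
#' half-width is reported at the design centre:
#' `t(0.975, n-2) * s * sqrt(1 + 1/n)`.
#'
#' @param records data.frame with columns `age_days` and `amplitude_uV`
#'   (a single stimulus; the `stimulus` column, if present, must be
#'   constant).
#' @param floor_policy `"drop"` or `"censor"`.
#' @param noise_floor amplitude floor (uV); records with amplitude <= floor
#'   are subject to `floor_policy`.  `NULL` disables floor handling.
#' @return a [decay_fit()].
#' @export
fit_decay <- function(records, floor_policy = c("drop", "censor"),
                      noise_floor = NULL) {
  floor_policy <- match.arg(floor_policy)
  check_that(all(c("age_days", "amplitude_uV") %in% names(records)),
             "records need columns age_days, amplitude_uV")
  if ("stimulus" %in% names(records)) {
    stim <- unique(records$stimulus)
    check_that(length(stim) == 1L,
               "records must contain a single stimulus; got: ",
               paste(stim, collapse = ", "))
  } else stim <- "UV"
  age <- records$age_days
  amp <- records$amplitude_uV
  if (!is.null(noise_floor)) {
    at_floor <- amp <= noise_floor
    check_that(!all(at_floor), "all records at or below the noise floor")
    if (floor_policy == "drop") {
      age <- age[!at_floor]; amp <- amp[!at_floor]
    } else {
      amp <- pmax(amp, noise_floor)
    }
  }
  check_that(length(age) >= 3L, "need >= 3 records above the noise floor")
  check_that(all(amp > 0), "amplitudes must be positive to log-transform")
  y <- log10(amp)
  fit <- stats::lm(y ~ age)
  n <- length(age)
  s <- summary(fit)$sigma
  hw <- stats::qt(0.975, n - 2L) * s * sqrt(1 + 1 / n)
  decay_fit(slope = unname(stats::coef(fit)[2L]),
            intercept = unname(stats::coef(fit)[1L]),
            residual_sd = s, pi95_halfwidth = hw, n = n, stimulus = stim,
            age_range = range(age), age_center = mean(age),
            sxx = sum((age - mean(age))^2))
}

#' Daily percentage decline implied by a decay fit
#'
#' `100 * (1 - 10^slope)`: the per-day fractional amplitude loss of an
#' exponential decay with the fitted log10 slope.
#'
#' @param fit a [decay_fit()] with `slope <= 0`.
#' @return percent per day.
#' @export
percent_per_day <- function(fit) {
  check_that(fit$slope <= 0, "slope must be <= 0")
  100 * (1 - 10^fit$slope)
}

#' Predicted amplitude and 95% prediction interval at an age
#'
#' Mean = `10^(intercept + slope * age)`.  Interval endpoints are
#' `10^(fitted +- halfwidth)`, with the half-width either held constant at
#' its design-centre value (`"constant"`, the usual reported approximation)
#' or widened with distance from the design centre (`"exact"`, requires the
#' fit to carry `age_center`/`sxx`).
#'
#' @param fit a [decay_fit()].
#' @param age age in days.
#' @param interval `"constant"` or `"exact"`.
#' @return list with `mean_uV`, `pi_low_uV`, `pi_high_uV`, `log_mean`,
#'   `log_halfwidth`.  A warning is issued when `age` lies more than 20%
#'   outside the fitted range.
#' @export
predict_amplitude <- function(fit, age, interval = c("constant", "exact")) {
  interval <- match.arg(interval)
  check_that(inherits(fit, "decay_fit"), "fit must be a decay_fit")
  if (!is.null(fit$age_range)) {
    span <- diff(fit$age_range)
    if (age < fit$age_range[1] - 0.2 * span ||
        age > fit$age_range[2] + 0.2 * span)
      warning("predict_amplitude: age ", age,
              " is an extrapolation beyond the fitted range")
  }
  yhat <- fit$intercept + fit$slope * age
  hw <- fit$pi95_halfwidth
  if (interval == "exact") {
    check_that(!is.null(fit$age_center) && !is.null(fit$sxx),
               "exact interval needs age_center and sxx in the fit")
    hw <- stats::qt(0.975, fit$n - 2L) * fit$residual_sd *
      sqrt(1 + 1 / fit$n + (age - fit$age_center)^2 / fit$sxx)
  }
  list(mean_uV = 10^yhat, pi_low_uV = 10^(yhat - hw),
       pi_high_uV = 10^(yhat + hw), log_mean = yhat, log_halfwidth = hw)
}

#' Plan a uniocular treatment window
#'
#' Given the fitted natural-history decay, an injection age and an
#' assessment delay, computes the expected untreated-eye amplitude at the
#' assessment age and the efficacy/toxicity thresholds implied by the
#' normal interocular asymmetry bound: `10^(log10(mean) +- asym_log)`.
#' A treated eye above the efficacy threshold is better than interocular
#' asymmetry can explain; below the toxicity threshold, worse.
#'
#' @param fit a [decay_fit()].
#' @param inject_age injection age (days).
#' @param assess_delay days between injection and ERG assessment.
#' @param asym_log interocular asymmetry bound, log10 units (> 0).
#' @param noise_floor optional floor (uV); a flag is set when the expected
#'   mean falls below it (window too late).
#' @return object of class `treatment_window` with `inject_age`,
#'   `assess_age`, `expected_untreated_mean`, `efficacy_threshold`,
#'   `toxicity_threshold`, `asym_log`, `below_floor`.
#' @export
plan_window <- function(fit, inject_age, assess_delay, asym_log = 0.3,
                        noise_floor = NULL) {
  check_that(asym_log > 0, "asym_log must be > 0")
  assess_age <- inject_age + assess_delay
  pred <- predict_amplitude(fit, assess_age)
  m <- pred$mean_uV
  below <- !is.null(noise_floor) && m < noise_floor
  if (below) warning("plan_window: expected untreated mean ", signif(m, 3),
                     " uV is below the noise floor; window too late")
  structure(list(
    inject_age = inject_age, assess_age = assess_age,
    expected_untreated_mean = m,
    efficacy_threshold = 10^(log10(m) + asym_log),
    toxicity_threshold = 10^(log10(m) - asym_log),
    asym_log = asym_log, below_floor = below
  ), class = "treatment_window")
}

#' Classify a treated eye against the interocular-asymmetry window
#'
#' @param treated,untreated amplitudes (uV), both > 0 (the untreated value
#'   is recorded for reporting; classification uses the planned thresholds).
#' @param window a [plan_window()] result.
#' @return `"efficacy"`, `"toxicity"` or `"within_asymmetry"`.
#' @export
classify_interocular <- function(treated, untreated, window) {
  check_that(treated > 0 && untreated > 0, "amplitudes must be > 0")
  if (treated > window$efficacy_threshold) "efficacy"
  else if (treated < window$toxicity_threshold) "toxicity"
  else "within_asymmetry"
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "<decay_fit> %s: log10(uV) = %.4f %+.6f * age; s = %.4f, PI95 +-%.3f, n = %d\n",
    x$stimulus, x$intercept, x$slope, x$residual_sd, x$pi95_halfwidth, x$n))
  invisible(x)
}

#' @export
print.treatment_window <- function(x, ...) {
  cat(sprintf(
    "<treatment_window> inject P%g, assess P%g: expect %.1f uV untreated; efficacy > %.1f uV, toxicity < %.1f uV (+-%.2f log)\n",
    x$inject_age, x$assess_age, x$expected_untreated_mean,
    x$efficacy_threshold, x$toxicity_threshold, x$asym_log))
  invisible(x)
}
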