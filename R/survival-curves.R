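#' Parametric survival curve specification
#'
#' Constructs a parametric survival law used to extrapolate overall survival
#' (OS) or progression-free survival (PFS) over the model horizon. Time is
#' measured in months throughout. The log-logistic family, used for all four
#' base-case curves, is parameterized as
#' \deqn{S(t) = 1 / (1 + (t/\lambda)^\gamma)}
#' so that the scale \eqn{\lambda} equals the median survival time in months.
#'
#' @param family One of `"log-logistic"`, `"weibull"`, `"log-normal"`,
#'   `"gompertz"`, `"gamma"`, `"exponential"`.
#' @param scale Positive scale parameter in months. For the log-logistic and
#'   log-normal families this is the median. Not used by the exponential and
#'   gompertz families, which are rate-parameterized.
#' @param shape Positive dimensionless shape parameter. Absent for the
#'   exponential family.
#' @param rate Positive rate per month, for the exponential and gompertz
#'   families.
#'
#' @return An object of class `surv_spec`.
#' @examples
#' os <- surv_spec("log-logistic", scale = 24.217, shape = 1.546)
#' survival_prob(os, c(0, 24.217, 60))
#' @export
surv_spec <- function(family, scale = NULL, shape = NULL, rate = NULL) {
  family <- match.arg(family, SURV_FAMILIES)
  if (family == "exponential") {
    assert_that(is_number(rate) && rate > 0,
      "exponential family requires a positive 'rate' (per month)")
    spec <- list(family = family, rate = rate)
  } else if (family == "gompertz") {
    assert_that(is_number(rate) && rate > 0,
      "gompertz family requires a positive 'rate' (per month)")
    assert_that(is_number(shape) && is.finite(shape) && shape != 0,
      "gompertz family requires a nonzero 'shape'")
    spec <- list(family = family, shape = shape, rate = rate)
  } else {
    assert_that(is_number(scale) && scale > 0,
      "'scale' must be a positive number (months), got %s", format(scale))
    assert_that(is_number(shape) && shape > 0,
      "'shape' must be a positive number, got %s", format(shape))
    spec <- list(family = family, scale = scale, shape = shape)
  }
  structure(spec, class = "surv_spec")
}

SURV_FAMILIES <- c("log-logistic", "weibull", "log-normal",
                   "gompertz", "gamma", "exponential")

#' @export
print.surv_spec <- function(x, ...) {
  pars <- vapply(x[setdiff(names(x), "family")],
                 function(p) format(p, digits = 6), character(1))
  cat(sprintf("<surv_spec> %s(%s)\n", x$family,
              paste(names(pars), pars, sep = " = ", collapse = ", ")))
  invisible(x)
}

#' Survivor function of a parametric curve
#'
#' Evaluates S(t), the probability of being event-free at `t` months.
#' Closed forms per family; the log-logistic form is
#' `1 / (1 + (t/scale)^shape)`.
#'
#' @param spec A [surv_spec()] or an object with an `hr`-transformed curve
#'   (see [apply_hazard_ratio()]).
#' @param t Vector of non-negative times in months.
#' @return Vector of survival probabilities in `[0, 1]`.
#' @export
survival_prob <- function(spec, t) UseMethod("survival_prob")

#' @export
survival_prob.surv_spec <- function(spec, t) {
  assert_that(is.numeric(t) && all(is.finite(t)) && all(t >= 0),
    "'t' must be non-negative and finite (months)")
  switch(spec$family,
    "log-logistic" = 1 / (1 + (t / spec$scale)^spec$shape),
    "weibull" = exp(-(t / spec$scale)^spec$shape),
    "log-normal" = stats::plnorm(t, meanlog = log(spec$scale),
                                 sdlog = spec$shape, lower.tail = FALSE),
    "gompertz" = flexsurv::pgompertz(t, shape = spec$shape, rate = spec$rate,
                                     lower.tail = FALSE),
    "gamma" = stats::pgamma(t, shape = spec$shape, scale = spec$scale,
                            lower.tail = FALSE),
    "exponential" = exp(-spec$rate * t)
  )
}

#' @export
survival_prob.ph_curve <- function(spec, t) {
  survival_prob(spec$baseline, t)^spec$hr
}

#' @export
survival_prob.function <- function(spec, t) {
  s <- spec(t)
  assert_that(all(s >= -1e-12 & s <= 1 + 1e-12),
    "survival function returned values outside [0, 1]")
  pmin(pmax(s, 0), 1)
}

#' Quantile (inverse survivor) function
#'
#' Returns the time at which the survivor function reaches probability `p`.
#' Used by the pseudo-IPD simulator; the log-logistic inverse CDF is
#' `t = scale * ((1 - u)/u)^(1/shape)` for survivor level `u`.
#'
#' @param spec A [surv_spec()].
#' @param p Survivor probabilities in (0, 1).
#' @return Times in months with `survival_prob(spec, t) = p`.
#' @keywords internal
surv_quantile <- function(spec, p) {
  assert_that(all(p > 0 & p < 1), "'p' must lie in (0, 1)")
  switch(spec$family,
    "log-logistic" = spec$scale * ((1 - p) / p)^(1 / spec$shape),
    "weibull" = spec$scale * (-log(p))^(1 / spec$shape),
    "log-normal" = stats::qlnorm(p, meanlog = log(spec$scale),
                                 sdlog = spec$shape, lower.tail = FALSE),
    "gompertz" = flexsurv::qgompertz(p, shape = spec$shape, rate = spec$rate,
                                     lower.tail = FALSE),
    "gamma" = stats::qgamma(p, shape = spec$shape, scale = spec$scale,
                            lower.tail = FALSE),
    "exponential" = -log(p) / spec$rate
  )
}

#' Median survival time
#'
#' Time in months at which the survivor function crosses 0.5. Closed form
#' where available (for the log-logistic this is the scale parameter),
#' otherwise bisection to 1e-8 months.
#'
#' @param spec A [surv_spec()].
#' @return Median survival in months.
#' @export
median_survival <- function(spec) {
  med <- switch(spec$family,
    "log-logistic" = spec$scale,
    "log-normal" = spec$scale,
    "weibull" = spec$scale * log(2)^(1 / spec$shape),
    "exponential" = log(2) / spec$rate,
    NULL
  )
  if (!is.null(med)) return(med)
  # gompertz / gamma: numeric inversion
  upper <- 1
  while (survival_prob(spec, upper) > 0.5 && upper < 1e8) upper <- upper * 2
  stats::uniroot(function(t) survival_prob(spec, t) - 0.5,
                 lower = 0, upper = upper, tol = 1e-8)$root
}

#' Proportional-hazards transformation of a survivor curve
#'
#' Under proportional hazards with hazard ratio `hr`, the survivor function
#' transforms as `S(t)^hr`. Used to synthesize subgroup-specific intervention
#' curves from the comparator curve and the subgroup OS hazard ratio.
#'
#' @param baseline A [surv_spec()] (or any object `survival_prob` accepts).
#' @param hr Positive hazard ratio.
#' @return An object of class `ph_curve`; evaluate with [survival_prob()].
#' @examples
#' base <- surv_spec("log-logistic", scale = 17.255, shape = 1.718)
#' sub <- apply_hazard_ratio(base, 0.61)
#' survival_prob(sub, 12)
#' @export
apply_hazard_ratio <- function(baseline, hr) {
  assert_that(is_number(hr) && hr > 0, "'hr' must be a positive number")
  structure(list(baseline = baseline, hr = hr), class = "ph_curve")
}

#' @export
print.ph_curve <- function(x, ...) {
  cat(sprintf("<ph_curve> hr = %s applied to:\n  ", format(x$hr)))
  print(x$baseline)
  invisible(x)
}
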