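FLEXSURV_DIST <- c(
  "log-logistic" = "llogis",
  "weibull" = "weibull",
  "log-normal" = "lnorm",
  "gompertz" = "gompertz",
  "gamma" = "gamma",
  "exponential" = "exp"
)

#' Fit a parametric survival family to pseudo-IPD
#'
#' Maximum-likelihood fitting under right censoring (density contribution for
#' events, survivor contribution for censored observations), delegated to
#' [flexsurv::flexsurvreg()]. Fitted coefficients are mapped back onto the
#' package's month-scale parameterization (for the log-logistic, scale =
#' median in months).
#'
#' @param ipd A `pseudo_ipd` data frame (see [simulate_ipd()]); needs at
#'   least two observed events.
#' @param family One of the six candidate families.
#' @return A `fit_result` list: `spec` ([surv_spec()]), `loglik`, `aic`,
#'   `bic`, `n`, `n_events`, `converged`, `family`.
#' @export
fit_parametric <- function(ipd, family) {
  validate_ipd(ipd)
  family <- match.arg(family, SURV_FAMILIES)
  n_events <- sum(ipd$event)
  assert_that(n_events >= 2,
    "fitting requires at least 2 observed events, got %d", n_events)
  fit <- tryCatch(
    flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1, data = ipd,
                          dist = FLEXSURV_DIST[[family]]),
    error = function(e) stop_input("fit of %s family failed: %s",
                                   family, conditionMessage(e))
  )
  pars <- stats::setNames(fit$res[, "est"], rownames(fit$res))
  spec <- switch(family,
    "log-logistic" = surv_spec(family, scale = pars[["scale"]],
                               shape = pars[["shape"]]),
    "weibull" = surv_spec(family, scale = pars[["scale"]],
                          shape = pars[["shape"]]),
    "log-normal" = surv_spec(family, scale = exp(pars[["meanlog"]]),
                             shape = pars[["sdlog"]]),
    "gompertz" = surv_spec(family, shape = pars[["shape"]],
                           rate = pars[["rate"]]),
    "gamma" = surv_spec(family, scale = 1 / pars[["rate"]],
                        shape = pars[["shape"]]),
    "exponential" = surv_spec(family, rate = pars[["rate"]])
  )
  k <- fit$npars
  ll <- fit$loglik
  structure(list(
    family = family,
    spec = spec,
    loglik = ll,
    aic = -2 * ll + 2 * k,
    bic = -2 * ll + k * log(nrow(ipd)),
    n = nrow(ipd),
    n_events = n_events,
    converged = is.finite(ll) && all(is.finite(pars))
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s: loglik %.3f, AIC %.2f, BIC %.2f (n = %d, events = %d)%s\n",
              x$family, x$loglik, x$aic, x$bic, x$n, x$n_events,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Select the best-fitting family by information criteria
#'
#' The family minimizing AIC wins; AIC ties are broken by lower BIC, and
#' residual ties by the fixed family order log-logistic, weibull, log-normal,
#' gompertz, gamma, exponential.
#'
#' @param fits A list of converged `fit_result` objects (see
#'   [fit_parametric()]).
#' @return The selected family name.
#' @export
select_best <- function(fits) {
  assert_that(length(fits) >= 1, "'fits' must contain at least one fit")
  fits <- Filter(function(f) isTRUE(f$converged), fits)
  assert_that(length(fits) >= 1, "no converged fits to select from")
  fam <- vapply(fits, function(f) f$family, character(1))
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  bic <- vapply(fits, function(f) f$bic, numeric(1))
  ord <- order(aic, bic, match(fam, SURV_FAMILIES))
  fam[ord[1]]
}
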