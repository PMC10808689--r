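#' Gamma distribution moment-matched to a mean and 95% bounds
#'
#' Cost parameters are sampled from gamma distributions whose standard
#' deviation is derived from the reported bounds read as a 95% interval:
#' `sd = (upper - lower) / 3.92` (divisor configurable).
#'
#' @param mean Positive mean.
#' @param lower,upper Bounds with `0 < lower <= mean <= upper`.
#' @param divisor Range-to-sd divisor (default `2 * 1.96`).
#' @return List with `shape` and `scale` (mean = shape x scale).
#' @export
gamma_from_mean_bounds <- function(mean, lower, upper, divisor = 3.92) {
  assert_that(is_number(mean) && mean > 0, "'mean' must be > 0")
  assert_that(lower > 0 && lower <= mean && mean <= upper,
    "bounds must satisfy 0 < lower <= mean <= upper")
  sd <- (upper - lower) / divisor
  list(shape = mean^2 / sd^2, scale = sd^2 / mean)
}

#' Beta distribution moment-matched to a mean and 95% bounds
#'
#' Utility and probability parameters are sampled from beta distributions
#' moment-matched to the mean and `sd = (upper - lower) / 3.92`. The
#' disutility magnitude and the discount rate (rescaled onto its 0-8% range)
#' use the same machinery.
#'
#' @inheritParams gamma_from_mean_bounds
#' @return List with `alpha` and `beta`.
#' @export
beta_from_mean_bounds <- function(mean, lower, upper, divisor = 3.92) {
  assert_that(is_number(mean) && mean > 0 && mean < 1,
    "'mean' must lie in (0, 1)")
  assert_that(lower <= mean && mean <= upper && lower >= 0 && upper <= 1,
    "bounds must satisfy 0 <= lower <= mean <= upper <= 1")
  sd <- (upper - lower) / divisor
  v <- sd^2
  assert_that(v < mean * (1 - mean),
    "infeasible moments: variance %.4g >= mean(1-mean) = %.4g",
    v, mean * (1 - mean))
  nu <- mean * (1 - mean) / v - 1
  list(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Enumerate the sensitivity-analysis parameter set
#'
#' Every cost, utility, and adverse-event-risk input, plus the discount
#' rate. Bounds are +/-20% of the base value (for the disutility, of its
#' magnitude); the discount rate ranges over 0-8%. The `dist` column drives
#' the probabilistic analysis: `gamma` for costs, `beta` for utilities and
#' risks, `beta_scaled` for the discount rate, `neg_beta` for the
#' disutility.
#'
#' @param config A `psmcea_config`.
#' @return Data frame with columns `path`, `base`, `lower`, `upper`, `dist`.
#' @export
sensitivity_parameters <- function(config) {
  rows <- list()
  add <- function(path, dist, lower = NULL, upper = NULL) {
    base <- config_get(config, path)
    rows[[length(rows) + 1]] <<- data.frame(
      path = path, base = base,
      lower = lower %||% (0.8 * base), upper = upper %||% (1.2 * base),
      dist = dist
    )
  }
  for (d in names(config$drugs)) add(paste0("drugs.", d, ".price_per_vial"), "gamma")
  for (nm in names(config$admin)) add(paste0("admin.", nm), "gamma")
  for (nm in names(config$labs)) add(paste0("labs.", nm), "gamma")
  add("imaging.ct", "gamma")
  for (nm in names(config$ae$costs)) add(paste0("ae.costs.", nm), "gamma")
  for (arm in ARMS) for (nm in names(config$ae$risks[[arm]]))
    add(paste0("ae.risks.", arm, ".", nm), "beta")
  add("terminal.bsc_per_cycle", "gamma")
  add("terminal.eol_once", "gamma")
  add("utilities.pf", "beta")
  add("utilities.pd", "beta")
  du <- config$utilities$ae_disutility
  rows[[length(rows) + 1]] <- data.frame(
    path = "utilities.ae_disutility", base = du,
    lower = 1.2 * du, upper = 0.8 * du, dist = "neg_beta"
  )
  add("settings.discount_annual", "beta_scaled", lower = 0, upper = 0.08)
  do.call(rbind, rows)
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Each parameter is moved to its lower and upper bound in turn, all others
#' held at base, and the incremental comparison recomputed. Rows are sorted
#' by decreasing ICER spread for tornado rendering. Dominance at a bound is
#' recorded in the status columns and yields an `NA` ICER.
#'
#' @param config A `psmcea_config`.
#' @param parameters Optional subset, a data frame as from
#'   [sensitivity_parameters()].
#' @param pricing Pricing scenario override.
#' @return Data frame with per-parameter ICERs at each bound and the spread.
#' @export
one_way_dsa <- function(config, parameters = NULL, pricing = NULL) {
  pars <- parameters %||% sensitivity_parameters(config)
  eval_at <- function(path, value) {
    cfg <- config_set(config, path, value)
    res <- run_base_case(cfg, pricing)
    c(icer = res$icer, status = res$status)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(pars)), function(i) {
    lo <- eval_at(pars$path[i], pars$lower[i])
    hi <- eval_at(pars$path[i], pars$upper[i])
    data.frame(
      parameter = pars$path[i], base = pars$base[i],
      lower = pars$lower[i], upper = pars$upper[i],
      icer_at_lower = as.numeric(lo[["icer"]]),
      icer_at_upper = as.numeric(hi[["icer"]]),
      status_at_lower = lo[["status"]], status_at_upper = hi[["status"]]
    )
  }))
  out$spread <- abs(out$icer_at_upper - out$icer_at_lower)
  out[order(-out$spread), ]
}

draw_parameter <- function(row, n, divisor) {
  base <- row$base
  if (row$dist == "gamma") {
    if (base <= 0 || row$upper == row$lower) return(rep(base, n))
    g <- gamma_from_mean_bounds(base, row$lower, row$upper, divisor)
    stats::rgamma(n, shape = g$shape, scale = g$scale)
  } else if (row$dist == "beta") {
    if (base <= 0 || base >= 1 || row$upper == row$lower) return(rep(base, n))
    b <- beta_from_mean_bounds(base, row$lower, row$upper, divisor)
    stats::rbeta(n, b$alpha, b$beta)
  } else if (row$dist == "neg_beta") {
    m <- abs(base)
    b <- beta_from_mean_bounds(m, 0.8 * m, 1.2 * m, divisor)
    -stats::rbeta(n, b$alpha, b$beta)
  } else if (row$dist == "beta_scaled") {
    span <- row$upper - row$lower
    m <- (base - row$lower) / span
    b <- beta_from_mean_bounds(m, 0, 1, divisor)
    row$lower + span * stats::rbeta(n, b$alpha, b$beta)
  } else {
    stop_input("unknown sampling distribution '%s'", row$dist)
  }
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo analysis drawing all cost, utility, adverse-event-risk, and
#' discount-rate parameters jointly from their distributions in each
#' iteration (gamma for costs, beta for utilities and risks, scaled beta for
#' the discount rate), with the survival curves held at base. Each iteration
#' runs both model arms and records the incremental cost and QALYs.
#'
#' @param config A `psmcea_config`.
#' @param n Number of iterations (default 10,000).
#' @param seed Integer seed (required; same seed, same draws).
#' @param pricing Pricing scenario override.
#' @return A `psa_result` list: `draws` (data frame of `delta_cost`,
#'   `delta_qaly`), `n`, `seed`, `wtp`, `prob_cost_effective` at `wtp`.
#' @export
run_psa <- function(config, n = 10000, seed, pricing = NULL) {
  assert_that(is_number(n) && n >= 1, "'n' must be >= 1")
  assert_that(is_number(seed), "'seed' is required")
  pars <- sensitivity_parameters(config)
  divisor <- config$settings$psa_range_divisor
  set.seed(as.integer(seed))
  draws <- lapply(seq_len(nrow(pars)),
                  function(i) draw_parameter(pars[i, ], n, divisor))
  names(draws) <- pars$path
  # survival curves fixed at base in the PSA, so the traces are fixed too
  traces <- lapply(ARMS, function(arm) {
    build_trace(do.call(surv_spec, config$survival$os[[arm]]),
                do.call(surv_spec, config$survival$pfs[[arm]]),
                config$settings)
  })
  names(traces) <- ARMS
  dc <- dq <- numeric(n)
  for (it in seq_len(n)) {
    cfg <- config
    for (p in pars$path) cfg <- config_set(cfg, p, draws[[p]][it])
    oi <- accrue(traces$intervention, cfg, "intervention", pricing)
    oc <- accrue(traces$comparator, cfg, "comparator", pricing)
    dc[it] <- oi$total_cost - oc$total_cost
    dq[it] <- oi$total_qalys - oc$total_qalys
  }
  wtp <- config$settings$wtp
  structure(list(
    draws = data.frame(delta_cost = dc, delta_qaly = dq),
    parameter_draws = draws,
    n = n, seed = seed, wtp = wtp,
    prob_cost_effective = mean(wtp * dq - dc > 0)
  ), class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf(
    "<psa_result> %d draws (seed %s): P(cost-effective at WTP %s) = %.2f%%\n",
    x$n, format(x$seed), format(x$wtp, big.mark = ","),
    100 * x$prob_cost_effective))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws with
#' positive incremental net monetary benefit.
#'
#' @param psa A `psa_result`.
#' @param wtp_grid Vector of WTP values, USD/QALY; defaults to a grid from 0
#'   to 4x the configured threshold that includes the threshold itself.
#' @return Data frame with columns `wtp` and `probability`.
#' @export
ceac <- function(psa, wtp_grid = NULL) {
  assert_that(nrow(psa$draws) >= 1, "PSA has no draws")
  wtp_grid <- wtp_grid %||%
    sort(unique(c(seq(0, 4 * psa$wtp, length.out = 41), psa$wtp)))
  prob <- vapply(wtp_grid, function(w) {
    mean(w * psa$draws$delta_qaly - psa$draws$delta_cost > 0)
  }, numeric(1))
  data.frame(wtp = wtp_grid, probability = prob)
}
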