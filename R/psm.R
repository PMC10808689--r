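#' Build the three-state occupancy trace
#'
#' Partitioned survival: at each cycle's evaluation time the progression-free
#' share is the PFS survivor, the progressed share is OS minus PFS, and the
#' dead share the OS complement. Where the PFS curve exceeds the OS curve the
#' progression-free share is clamped to OS (with a warning), so occupancy
#' always sums to one. Incident progression and death per cycle are
#' successive differences of the cumulative curves at cycle ends, floored at
#' zero.
#'
#' @param os_curve,pfs_curve A [surv_spec()], [apply_hazard_ratio()] result,
#'   or survivor function of time in months.
#' @param settings Model settings list (`cycle_days`, `n_cycles`,
#'   `occupancy_eval` among `"start"`, `"end"`, `"midpoint"`).
#' @param warn_clamp Warn when the PFS curve exceeds the OS curve and is
#'   clamped. The subgroup analysis disables the warning because its
#'   proportional-hazards OS construction makes mild clamping an expected,
#'   documented feature.
#' @return A `psm_trace` data frame with one row per cycle: `cycle`,
#'   `t_eval_months`, `pf`, `pd`, `dead`, `incident_progression`,
#'   `incident_death`.
#' @export
build_trace <- function(os_curve, pfs_curve, settings, warn_clamp = TRUE) {
  k <- seq_len(settings$n_cycles)
  cyc_months <- days_to_months(settings$cycle_days)
  offset <- switch(settings$occupancy_eval %||% "start",
                   start = 1, end = 0, midpoint = 0.5)
  t_eval <- (k - offset) * cyc_months
  os <- survival_prob(os_curve, t_eval)
  pfs <- survival_prob(pfs_curve, t_eval)
  if (warn_clamp && any(pfs > os + 1e-12)) {
    warning("PFS exceeds OS at some evaluation times; progression-free ",
            "occupancy clamped to OS", call. = FALSE)
  }
  pf <- pmin(pfs, os)
  pd <- os - pf
  dead <- 1 - os
  t_end <- k * cyc_months
  os_end <- survival_prob(os_curve, t_end)
  pfs_end <- pmin(survival_prob(pfs_curve, t_end), os_end)
  incident_death <- pmax(-diff(c(1, os_end)), 0)
  incident_progression <- pmax(-diff(c(1, pfs_end)) - incident_death, 0)
  out <- data.frame(
    cycle = k, t_eval_months = t_eval, pf = pf, pd = pd, dead = dead,
    incident_progression = incident_progression,
    incident_death = incident_death
  )
  class(out) <- c("psm_trace", "data.frame")
  out
}

#' Per-cycle discount factor
#'
#' Discounting at the annual rate, applied to the time elapsed at the start
#' of the cycle: `(1 + rate)^(-(cycle_index - 1) * cycle_days / 365.25)`.
#'
#' @param cycle_index 1-based cycle number (vectorized).
#' @param settings Model settings (`cycle_days`, `discount_annual`).
#' @return Discount factors (1 at cycle 1).
#' @export
discount_factor <- function(cycle_index, settings) {
  assert_that(all(cycle_index >= 1), "'cycle_index' must be >= 1")
  days <- (cycle_index - 1) * settings$cycle_days
  (1 + settings$discount_annual)^(-days / DAYS_PER_YEAR)
}

#' Accrue discounted costs and QALYs over a trace
#'
#' Per cycle, against progression-free occupancy: drug acquisition (with the
#' component cycle caps), administration, and monitoring; against progressed
#' occupancy: best supportive care; per incident death the one-time
#' end-of-life cost; per incident progression the one-time consultation
#' cost. QALYs accrue as utility-weighted occupancy times the cycle length
#' in years. The expected adverse-event cost and QALY loss are borne once in
#' cycle 1.
#'
#' @param trace A `psm_trace` from [build_trace()].
#' @param config A `psmcea_config`.
#' @param arm `"intervention"` or `"comparator"`.
#' @param pricing `"original"` or `"donation"`; defaults to the config
#'   setting.
#' @return An `arm_outcome` list: `total_cost`, `total_qalys`, `total_ly`
#'   (all discounted), and `cost_breakdown`.
#' @export
accrue <- function(trace, config, arm, pricing = NULL) {
  arm <- match.arg(arm, ARMS)
  st <- config$settings
  k <- trace$cycle
  disc <- discount_factor(k, st)
  cycle_years <- st$cycle_days / DAYS_PER_YEAR
  u <- config$utilities

  drug <- sum(disc * trace$pf * drug_cost_per_cycle(config, arm, k, pricing))
  admin <- sum(disc * trace$pf * admin_cost_per_cycle(config))
  monitoring <- sum(disc * trace$pf * monitoring_cost(k, config))
  bsc <- sum(disc * trace$pd * config$terminal$bsc_per_cycle)
  eol <- sum(disc * trace$incident_death * config$terminal$eol_once)
  consult <- sum(disc * trace$incident_progression *
                   config$progression_consult_once)
  ae <- ae_burden(config, arm)
  ae_cost <- disc[1] * ae$cost

  breakdown <- c(drug = drug, administration = admin,
                 monitoring = monitoring, supportive_care = bsc,
                 end_of_life = eol, progression_consult = consult,
                 adverse_events = ae_cost)
  qalys <- sum(disc * (u$pf * trace$pf + u$pd * trace$pd +
                         u$dead * trace$dead) * cycle_years) -
    disc[1] * ae$qaly_loss
  ly <- sum(disc * (trace$pf + trace$pd) * cycle_years)
  structure(list(
    arm = arm,
    total_cost = sum(breakdown),
    total_qalys = qalys,
    total_ly = ly,
    cost_breakdown = breakdown
  ), class = "arm_outcome")
}

#' @export
print.arm_outcome <- function(x, ...) {
  cat(sprintf("<arm_outcome> %s: cost %s USD, %.3f QALYs, %.3f LYs\n",
              x$arm, format(round(x$total_cost, 2), big.mark = ","),
              x$total_qalys, x$total_ly))
  invisible(x)
}

#' Run one model arm end to end
#'
#' Builds the occupancy trace from the arm's configured OS and PFS curves
#' and accrues discounted costs and QALYs.
#'
#' @param config A `psmcea_config`.
#' @param arm `"intervention"` or `"comparator"`.
#' @param pricing Pricing scenario override.
#' @param os_curve,pfs_curve Optional curve overrides (used by the subgroup
#'   analysis).
#' @param warn_clamp Passed to [build_trace()].
#' @return An `arm_outcome`.
#' @export
run_arm <- function(config, arm, pricing = NULL,
                    os_curve = NULL, pfs_curve = NULL, warn_clamp = TRUE) {
  arm <- match.arg(arm, ARMS)
  os_curve <- os_curve %||% do.call(surv_spec, config$survival$os[[arm]])
  pfs_curve <- pfs_curve %||% do.call(surv_spec, config$survival$pfs[[arm]])
  trace <- build_trace(os_curve, pfs_curve, config$settings, warn_clamp)
  accrue(trace, config, arm, pricing)
}

#' Export a trace to CSV
#'
#' @param trace A `psm_trace`.
#' @param path Output file.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
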