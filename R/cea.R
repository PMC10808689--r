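#' Incremental cost-effectiveness comparison of two arms
#'
#' Computes incremental cost and QALYs, classifies dominance, and reports the
#' ICER where meaningful. The intervention is *dominant* when it is no more
#' costly and no less effective (and differs), *dominated* in the mirror
#' case; otherwise the ICER is the incremental cost per incremental QALY.
#'
#' @param intervention,comparator `arm_outcome` objects from the same
#'   settings.
#' @param wtp Willingness-to-pay threshold, USD/QALY, for the net monetary
#'   benefit.
#' @return A `cea_result` list: `delta_cost`, `delta_qaly`, `icer` (numeric,
#'   `NA` when status is not `"icer"`), `status` in
#'   `c("icer", "dominant", "dominated", "undefined")`, `inmb` (incremental
#'   net monetary benefit at `wtp`).
#' @export
cea_compare <- function(intervention, comparator, wtp = NULL) {
  dc <- intervention$total_cost - comparator$total_cost
  dq <- intervention$total_qalys - comparator$total_qalys
  eps <- 0
  status <- if (dc <= eps && dq >= eps && !(dc == 0 && dq == 0)) {
    "dominant"
  } else if (dc >= eps && dq <= eps && !(dc == 0 && dq == 0)) {
    "dominated"
  } else if (dc == 0 && dq == 0) {
    "undefined"
  } else {
    "icer"
  }
  icer <- if (status == "icer") dc / dq else NA_real_
  inmb <- if (!is.null(wtp)) wtp * dq - dc else NA_real_
  structure(list(
    intervention = intervention, comparator = comparator,
    delta_cost = dc, delta_qaly = dq,
    icer = icer, status = status, wtp = wtp, inmb = inmb
  ), class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("<cea_result> dCost %s USD, dQALY %.3f -> %s\n",
              format(round(x$delta_cost, 2), big.mark = ","), x$delta_qaly,
              if (x$status == "icer")
                sprintf("ICER %s USD/QALY", format(round(x$icer, 2), big.mark = ","))
              else x$status))
  invisible(x)
}

#' Net monetary benefit
#'
#' `wtp x QALYs - cost` for a single arm outcome.
#'
#' @param outcome An `arm_outcome`.
#' @param wtp Willingness-to-pay, USD/QALY (>= 0).
#' @return USD.
#' @export
nmb <- function(outcome, wtp) {
  assert_that(is_number(wtp) && wtp >= 0, "'wtp' must be >= 0")
  wtp * outcome$total_qalys - outcome$total_cost
}

#' Run the base-case analysis for one pricing scenario
#'
#' @param config A `psmcea_config`.
#' @param pricing `"original"` or `"donation"`; defaults to the config
#'   setting.
#' @return A `cea_result` comparing intervention vs comparator.
#' @export
run_base_case <- function(config, pricing = NULL) {
  intervention <- run_arm(config, "intervention", pricing)
  comparator <- run_arm(config, "comparator", pricing)
  cea_compare(intervention, comparator, wtp = config$settings$wtp)
}

#' Tabulate a base-case comparison
#'
#' Two arm rows plus one incremental row, shaped like a standard
#' cost-effectiveness results table.
#'
#' @param result A `cea_result`.
#' @return A data frame with columns `arm`, `total_cost`, `total_qalys`,
#'   `icer`.
#' @export
base_case_table <- function(result) {
  data.frame(
    arm = c("intervention", "comparator", "incremental"),
    total_cost = c(result$intervention$total_cost,
                   result$comparator$total_cost, result$delta_cost),
    total_qalys = c(result$intervention$total_qalys,
                    result$comparator$total_qalys, result$delta_qaly),
    icer = c(NA, NA,
             if (result$status == "icer") result$icer else NA)
  )
}
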