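#' Dose in mg for a drug and patient profile
#'
#' Applies the dosing rule: `per_m2` doses by body surface area, `per_kg` by
#' weight, `flat` is a fixed dose.
#'
#' @param drug A drug entry from the configuration (price, vial size, dosing
#'   rule).
#' @param patient List with `bsa_m2` and `weight_kg`.
#' @return Dose in mg per administration.
#' @export
dose_mg <- function(drug, patient) {
  switch(drug$dose$rule,
    flat = drug$dose$amount,
    per_m2 = drug$dose$amount * patient$bsa_m2,
    per_kg = drug$dose$amount * patient$weight_kg,
    stop_input("unknown dosing rule '%s'", drug$dose$rule)
  )
}

#' Whole vials needed for a dose
#'
#' Surplus drug is discarded after infusion, so quantities are rounded up to
#' whole vials (wastage included in the acquisition cost).
#'
#' @param dose Dose in mg (>= 0).
#' @param vial_mg Vial size in mg (> 0).
#' @return Smallest integer vial count covering the dose.
#' @export
vials_needed <- function(dose, vial_mg) {
  assert_that(is_number(dose) && dose >= 0, "'dose' must be >= 0")
  assert_that(is_number(vial_mg) && vial_mg > 0, "'vial_mg' must be > 0")
  ceiling(dose / vial_mg)
}

#' Drug acquisition cost per cycle for one arm
#'
#' Sums vial-rounded acquisition costs over the arm's active components.
#' Pembrolizumab is scaled by the pricing multiplier (1 at the original
#' price, 0.414 under the charitable-donation policy); bevacizumab is
#' weighted by its per-arm uptake fraction. `cycle_index` enforces each
#' component's maximum cycle count.
#'
#' @param config A `psmcea_config`.
#' @param arm `"intervention"` or `"comparator"`.
#' @param cycle_index 1-based cycle number (vectorized).
#' @param pricing `"original"` or `"donation"`; defaults to the config
#'   setting.
#' @return USD per cycle (vector along `cycle_index`).
#' @export
drug_cost_per_cycle <- function(config, arm, cycle_index = 1,
                                pricing = NULL) {
  arm <- match.arg(arm, ARMS)
  mult <- price_multiplier(config, pricing)
  total <- numeric(length(cycle_index))
  for (nm in names(config$drugs)) {
    drug <- config$drugs[[nm]]
    if (!(arm %in% drug$arms)) next
    per_admin <- vials_needed(dose_mg(drug, config$patient), drug$vial_mg) *
      drug$price_per_vial
    if (nm == "pembrolizumab") per_admin <- per_admin * mult
    if (!is.null(drug$uptake)) per_admin <- per_admin * drug$uptake[[arm]]
    total <- total + per_admin * (cycle_index <= drug$max_cycles)
  }
  total
}

#' Administration cost per treatment cycle
#'
#' Hospitalization, preventive medication, and infusion fees.
#'
#' @param config A `psmcea_config`.
#' @return USD per cycle.
#' @export
admin_cost_per_cycle <- function(config) {
  sum(unlist(config$admin))
}

#' Monitoring (laboratory and imaging) cost for a cycle
#'
#' While on treatment each cycle carries ECG, hematology, serum chemistry,
#' urinalysis and coagulation tests; thyroid function is checked every two
#' cycles. Tumour imaging follows the trial schedule: first scan at week 9,
#' every 9 weeks through week 54, then every 12 weeks; a cycle bears the
#' scan cost when its start week (3 x (cycle_index - 1)) falls on the
#' schedule. Only a contrast-enhanced CT price is available, so every scan
#' is costed as CT.
#'
#' @param cycle_index 1-based cycle number (vectorized).
#' @param config A `psmcea_config`.
#' @param on_treatment Whether per-cycle labs apply.
#' @return USD for the cycle (vector along `cycle_index`).
#' @export
monitoring_cost <- function(cycle_index, config, on_treatment = TRUE) {
  assert_that(all(cycle_index >= 1), "'cycle_index' must be >= 1")
  labs <- config$labs
  per_cycle <- labs$ecg + labs$hematology + labs$serum_chemistry +
    labs$urinalysis + labs$coagulation
  thyroid <- ifelse(cycle_index %% 2 == 0, labs$thyroid, 0)
  img <- config$imaging
  week <- 3 * (cycle_index - 1)
  scan <- (week >= img$first_scan_week & week <= img$early_until_week &
             (week - img$first_scan_week) %% img$early_interval_weeks == 0) |
          (week > img$early_until_week &
             (week - img$early_until_week) %% img$late_interval_weeks == 0)
  lab_part <- if (on_treatment) per_cycle + thyroid else 0
  lab_part + scan * img$ct
}

#' One-time adverse-event burden for an arm
#'
#' Grade >= 3 adverse events are assumed to occur during the first treatment
#' cycle. The expected one-time cost is the risk-weighted sum of episode
#' costs; the expected QALY loss is the summed risk times the absolute
#' disutility, applied for one cycle's duration.
#'
#' @param config A `psmcea_config`.
#' @param arm `"intervention"` or `"comparator"`.
#' @return List with `cost` (USD) and `qaly_loss` (QALYs), both applied once.
#' @export
ae_burden <- function(config, arm) {
  arm <- match.arg(arm, ARMS)
  risks <- unlist(config$ae$risks[[arm]])
  costs <- unlist(config$ae$costs)[names(risks)]
  assert_that(!anyNA(costs), "every adverse-event risk needs an episode cost")
  cycle_years <- config$settings$cycle_days / DAYS_PER_YEAR
  list(
    cost = sum(risks * costs),
    qaly_loss = sum(risks) * abs(config$utilities$ae_disutility) * cycle_years
  )
}
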