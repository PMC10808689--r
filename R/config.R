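#' Default analysis configuration
#'
#' Returns the fully parameterized base-case configuration: log-logistic OS
#' and PFS curves per arm, drug prices and vial sizes, dosing rules,
#' administration / laboratory / imaging unit costs, grade >= 3 adverse-event
#' risks and episode costs, supportive and end-of-life costs, utilities, model
#' settings, and the subgroup hazard-ratio table. All monetary values are USD.
#'
#' `max_cycles = Inf` means a component is given until progression;
#' the chemotherapy backbone is capped at 6 cycles. Bevacizumab cost is
#' weighted by its per-arm uptake fraction.
#'
#' @return A nested list of class `psmcea_config`.
#' @export
default_config <- function() {
  cfg <- list(
    meta = list(currency = "USD", rmb_per_usd = 7.2897),
    survival = list(
      os = list(
        intervention = list(family = "log-logistic", scale = 24.217, shape = 1.546),
        comparator   = list(family = "log-logistic", scale = 17.255, shape = 1.718)
      ),
      pfs = list(
        intervention = list(family = "log-logistic", scale = 12.2045, shape = 1.4758),
        comparator   = list(family = "log-logistic", scale = 8.1898, shape = 1.7748)
      )
    ),
    patient = list(bsa_m2 = 1.62, weight_kg = 59),
    drugs = list(
      pembrolizumab = list(price_per_vial = 2457.99, vial_mg = 100,
                           dose = list(rule = "flat", amount = 200),
                           max_cycles = Inf, arms = "intervention"),
      paclitaxel = list(price_per_vial = 22.15, vial_mg = 30,
                        dose = list(rule = "per_m2", amount = 175),
                        max_cycles = 6, arms = c("intervention", "comparator")),
      cisplatin = list(price_per_vial = 2.62, vial_mg = 30,
                       dose = list(rule = "per_m2", amount = 50),
                       max_cycles = 6, arms = c("intervention", "comparator")),
      bevacizumab = list(price_per_vial = 158.85, vial_mg = 100,
                         dose = list(rule = "per_kg", amount = 15),
                         max_cycles = Inf, arms = c("intervention", "comparator"),
                         uptake = list(intervention = 0.636, comparator = 0.625))
    ),
    admin = list(hospitalization = 41.15, preventive_medication = 1.65,
                 infusion = 1.63),
    labs = list(ecg = 3.70, hematology = 3.43, serum_chemistry = 24.69,
                urinalysis = 4.12, coagulation = 9.13, thyroid = 20.58),
    imaging = list(ct = 336.09, first_scan_week = 9, early_interval_weeks = 9,
                   early_until_week = 54, late_interval_weeks = 12),
    ae = list(
      costs = list(
        anemia = 138.57, nausea = 20.13, diarrhea = 3.51, constipation = 4.04,
        arthralgia = 17.69, peripheral_neuropathy = 1.45, vomiting = 20.13,
        hypertension = 0.07, urinary_tract_infection = 126.03,
        neutropenia = 399.63, peripheral_sensory_neuropathy = 1.45,
        thrombocytopenia = 1094.70
      ),
      risks = list(
        intervention = list(
          anemia = 0.303, nausea = 0.020, diarrhea = 0.020,
          constipation = 0.003, arthralgia = 0.007,
          peripheral_neuropathy = 0.026, vomiting = 0.026,
          hypertension = 0.094, urinary_tract_infection = 0.088,
          neutropenia = 0.124, peripheral_sensory_neuropathy = 0.010,
          thrombocytopenia = 0.075
        ),
        comparator = list(
          anemia = 0.269, nausea = 0.016, diarrhea = 0.026,
          constipation = 0.010, arthralgia = 0.013,
          peripheral_neuropathy = 0.029, vomiting = 0.019,
          hypertension = 0.107, urinary_tract_infection = 0.081,
          neutropenia = 0.097, peripheral_sensory_neuropathy = 0.019,
          thrombocytopenia = 0.045
        )
      )
    ),
    terminal = list(bsc_per_cycle = 274.36, eol_once = 685.90),
    progression_consult_once = 0,
    utilities = list(pf = 0.76, pd = 0.52, dead = 0, ae_disutility = -0.28),
    settings = list(
      cycle_days = 21, n_cycles = 86, discount_annual = 0.05,
      wtp = 35268.94, gdp_per_capita = 11756.31,
      occupancy_eval = "start", pricing = "original",
      donation_multiplier = 0.414, psa_range_divisor = 3.92
    ),
    subgroups = list(
      list(label = "Age <65 years", hr = 0.64, lo = 0.50, hi = 0.82),
      list(label = "Age >=65 years", hr = 0.88, lo = 0.47, hi = 1.64),
      list(label = "White", hr = 0.68, lo = 0.50, hi = 0.91),
      list(label = "Non-White", hr = 0.70, lo = 0.47, hi = 1.04),
      list(label = "ECOG 0", hr = 0.68, lo = 0.49, hi = 0.96),
      list(label = "ECOG 1", hr = 0.68, lo = 0.50, hi = 0.94),
      list(label = "PD-L1 CPS <1", hr = 1.00, lo = 0.53, hi = 1.89),
      list(label = "PD-L1 CPS 1 to <10", hr = 0.67, lo = 0.46, hi = 0.97),
      list(label = "PD-L1 CPS >=10", hr = 0.61, lo = 0.44, hi = 0.84),
      list(label = "Concomitant bevacizumab: yes", hr = 0.63, lo = 0.47, hi = 0.87),
      list(label = "Concomitant bevacizumab: no", hr = 0.74, lo = 0.53, hi = 1.04),
      list(label = "Metastatic at diagnosis: yes", hr = 0.84, lo = 0.56, hi = 1.26),
      list(label = "Metastatic at diagnosis: no", hr = 0.61, lo = 0.46, hi = 0.80)
    )
  )
  class(cfg) <- c("psmcea_config", "list")
  validate_config(cfg)
}

ARMS <- c("intervention", "comparator")

# recursive merge of user values over defaults, rejecting unknown keys;
# unnamed lists (e.g. subgroups) are replaced wholesale
merge_config <- function(default, user, path = character()) {
  if (!is.list(user) || !is.list(default) ||
      is.null(names(default)) || is.null(names(user))) {
    return(user)
  }
  unknown <- setdiff(names(user), names(default))
  if (length(unknown) > 0) {
    stop_input("unknown configuration key(s): %s",
               paste(paste(c(path, unknown[1]), collapse = "."), collapse = ", "))
  }
  for (nm in names(user)) {
    default[[nm]] <- merge_config(default[[nm]], user[[nm]], c(path, nm))
  }
  default
}

#' Load an analysis configuration from JSON or YAML
#'
#' Values present in the file override the Table-1 defaults of
#' [default_config()]; omitted fields keep their defaults. Unknown keys and
#' schema violations raise errors naming the offending key.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A validated `psmcea_config`.
#' @export
load_config <- function(path) {
  assert_that(file.exists(path), "configuration file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  user <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE,
                               simplifyMatrix = FALSE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop_input("unsupported config format '.%s' (use .json or .yaml)", ext)
  )
  # "unbounded" is accepted for caps in JSON, which cannot carry Inf
  user <- rapply(user, function(x) {
    if (is.character(x) && length(x) == 1 && x == "unbounded") Inf else x
  }, how = "replace")
  cfg <- merge_config(unclass(default_config()), user)
  class(cfg) <- c("psmcea_config", "list")
  validate_config(cfg)
}

#' Write a configuration to YAML
#'
#' @param config A `psmcea_config`.
#' @param path Output path (`.yaml`).
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

check_num <- function(x, key, lo = -Inf, hi = Inf, allow_inf = FALSE) {
  ok <- !is.null(x) && is.numeric(x) && length(x) == 1 && !is.na(x) &&
    (allow_inf || is.finite(x)) && x >= lo && x <= hi
  assert_that(ok, "config key '%s' must be a number in [%s, %s], got %s",
              key, format(lo), format(hi),
              if (is.null(x)) "nothing" else format(x))
  invisible(x)
}

#' Validate an analysis configuration
#'
#' @param config A `psmcea_config`.
#' @return The config, invisibly erroring on the first violated constraint.
#' @export
validate_config <- function(config) {
  for (ep in c("os", "pfs")) for (arm in ARMS) {
    s <- config$survival[[ep]][[arm]]
    do.call(surv_spec, s) # errors if invalid
  }
  check_num(config$patient$bsa_m2, "patient.bsa_m2", lo = 1e-6)
  check_num(config$patient$weight_kg, "patient.weight_kg", lo = 1e-6)
  for (d in names(config$drugs)) {
    drug <- config$drugs[[d]]
    check_num(drug$price_per_vial, paste0("drugs.", d, ".price_per_vial"), lo = 0)
    check_num(drug$vial_mg, paste0("drugs.", d, ".vial_mg"), lo = 1e-9)
    assert_that(drug$dose$rule %in% c("flat", "per_m2", "per_kg"),
      "config key 'drugs.%s.dose.rule' must be flat/per_m2/per_kg", d)
    check_num(drug$dose$amount, paste0("drugs.", d, ".dose.amount"), lo = 1e-9)
    check_num(drug$max_cycles, paste0("drugs.", d, ".max_cycles"),
              lo = 0, allow_inf = TRUE)
    assert_that(all(drug$arms %in% ARMS),
      "config key 'drugs.%s.arms' must be a subset of %s",
      d, paste(ARMS, collapse = "/"))
  }
  for (nm in names(config$admin))
    check_num(config$admin[[nm]], paste0("admin.", nm), lo = 0)
  for (nm in names(config$labs))
    check_num(config$labs[[nm]], paste0("labs.", nm), lo = 0)
  check_num(config$imaging$ct, "imaging.ct", lo = 0)
  for (nm in names(config$ae$costs))
    check_num(config$ae$costs[[nm]], paste0("ae.costs.", nm), lo = 0)
  for (arm in ARMS) {
    risks <- config$ae$risks[[arm]]
    assert_that(setequal(names(risks), names(config$ae$costs)),
      "ae.risks.%s must have one entry per costed adverse event", arm)
    for (nm in names(risks))
      check_num(risks[[nm]], paste0("ae.risks.", arm, ".", nm), lo = 0, hi = 1)
  }
  check_num(config$terminal$bsc_per_cycle, "terminal.bsc_per_cycle", lo = 0)
  check_num(config$terminal$eol_once, "terminal.eol_once", lo = 0)
  check_num(config$progression_consult_once, "progression_consult_once", lo = 0)
  check_num(config$utilities$pf, "utilities.pf", lo = 0, hi = 1)
  check_num(config$utilities$pd, "utilities.pd", lo = 0, hi = 1)
  check_num(config$utilities$dead, "utilities.dead", lo = 0, hi = 1)
  check_num(config$utilities$ae_disutility, "utilities.ae_disutility",
            lo = -1, hi = 0)
  assert_that(config$utilities$ae_disutility < 0,
    "config key 'utilities.ae_disutility' must be negative")
  st <- config$settings
  check_num(st$cycle_days, "settings.cycle_days", lo = 1e-9)
  check_num(st$n_cycles, "settings.n_cycles", lo = 1)
  check_num(st$discount_annual, "settings.discount_annual", lo = 0, hi = 0.08)
  check_num(st$wtp, "settings.wtp", lo = 0)
  check_num(st$donation_multiplier, "settings.donation_multiplier",
            lo = 1e-9, hi = 1)
  assert_that(st$occupancy_eval %in% c("start", "end", "midpoint"),
    "config key 'settings.occupancy_eval' must be start/end/midpoint")
  assert_that(st$pricing %in% c("original", "donation"),
    "config key 'settings.pricing' must be 'original' or 'donation'")
  for (sg in config$subgroups) {
    check_num(sg$hr, paste0("subgroups[", sg$label, "].hr"), lo = 1e-9)
    assert_that(sg$lo <= sg$hr && sg$hr <= sg$hi,
      "subgroup '%s' must satisfy lo <= hr <= hi", sg$label)
  }
  invisible(config)
}

# pembrolizumab acquisition multiplier for a pricing scenario
price_multiplier <- function(config, pricing = NULL) {
  pricing <- pricing %||% config$settings$pricing
  assert_that(pricing %in% c("original", "donation"),
    "'pricing' must be 'original' or 'donation'")
  if (pricing == "donation") config$settings$donation_multiplier else 1
}

# dotted-path accessors used by the sensitivity machinery
config_get <- function(config, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  val <- config
  for (k in keys) {
    val <- val[[k]]
    if (is.null(val)) stop_input("config path not found: %s", path)
  }
  val
}

config_set <- function(config, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  expr <- Reduce(function(x, k) call("[[", x, k), keys, quote(config))
  eval(call("<-", expr, value))
  config
}
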