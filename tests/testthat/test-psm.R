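cfg <- default_config()

test_that("trace occupancy conserves probability and mortality is monotone", {
  for (ev in c("start", "end", "midpoint")) {
    st <- cfg$settings
    st$occupancy_eval <- ev
    tr <- build_trace(llogis_os_int(), llogis_pfs_int(), st)
    expect_equal(nrow(tr), 86)
    expect_true(all(abs(tr$pf + tr$pd + tr$dead - 1) < 1e-9))
    expect_true(all(diff(tr$dead) >= -1e-12))
    expect_true(all(tr$pf >= 0 & tr$pd >= 0 & tr$dead >= 0))
    expect_true(all(tr$incident_death >= 0 & tr$incident_progression >= 0))
  }
})

test_that("degenerate curves give the expected occupancies", {
  ones <- function(t) rep(1, length(t))
  tr <- build_trace(ones, ones, cfg$settings)
  expect_true(all(tr$pf == 1 & tr$pd == 0 & tr$dead == 0))
  expect_true(all(tr$incident_death == 0 & tr$incident_progression == 0))
  # OS == PFS -> nobody occupies the progressed state
  same <- build_trace(llogis_os_comp(), llogis_os_comp(), cfg$settings)
  expect_true(all(same$pd == 0))
})

test_that("PFS above OS is clamped with a warning", {
  expect_warning(
    tr <- build_trace(llogis_pfs_comp(), llogis_os_comp(), cfg$settings),
    "clamped"
  )
  expect_true(all(tr$pf + tr$pd + tr$dead - 1 < 1e-9 & tr$pd >= 0))
})

test_that("trace survivors match the closed-form curves at cycle ends", {
  st <- cfg$settings
  st$occupancy_eval <- "end"
  tr <- build_trace(llogis_os_comp(), llogis_pfs_comp(), st)
  t86 <- 86 * 21 / 30.4375
  # 1/(1 + (59.33/17.255)^1.718), computed independently
  expect_equal(1 - tr$dead[86], 0.10698748761400284, tolerance = 1e-10)
  expect_equal(tr$t_eval_months[86], t86)
})

test_that("discount factors follow the annual rate on elapsed days", {
  expect_equal(discount_factor(1, cfg$settings), 1)
  st0 <- cfg$settings
  st0$discount_annual <- 0
  expect_equal(discount_factor(1:86, st0), rep(1, 86))
  # cycle 18: 357 days elapsed, independently computed factor
  expect_equal(discount_factor(18, cfg$settings), 0.9534310895502573,
               tolerance = 1e-12)
})

test_that("zero utilities leave only the adverse-event QALY decrement", {
  cfg0 <- cfg
  cfg0$utilities$pf <- 0
  cfg0$utilities$pd <- 0
  out <- run_arm(cfg0, "intervention")
  expect_equal(out$total_qalys,
               -ae_burden(cfg0, "intervention")$qaly_loss)
})

test_that("undiscounted QALYs approximate the utility-weighted survival integral", {
  # rate 0, u_pf = u_pd = 1, no AEs: QALYs equal discretized restricted
  # mean survival; compare against a fine-grid integral of OS
  cfg1 <- cfg
  cfg1$settings$discount_annual <- 0
  cfg1$utilities$pf <- 1
  cfg1$utilities$pd <- 1
  for (arm in c("intervention", "comparator"))
    for (nm in names(cfg1$ae$risks[[arm]]))
      cfg1$ae$risks[[arm]][[nm]] <- 0
  out <- run_arm(cfg1, "comparator")
  os <- llogis_os_comp()
  fine <- seq(0, 86 * 21 / 30.4375, length.out = 20001)
  rmst_years <- sum((survival_prob(os, fine[-1]) +
                       survival_prob(os, fine[-length(fine)])) / 2 *
                      diff(fine)) / 12
  expect_equal(out$total_qalys, rmst_years, tolerance = 0.02)
  expect_equal(out$total_ly, rmst_years, tolerance = 0.02)
})

test_that("discounting never increases totals and rate 0 reproduces raw sums", {
  out_d <- run_arm(cfg, "intervention")
  cfg0 <- cfg
  cfg0$settings$discount_annual <- 0
  out_0 <- run_arm(cfg0, "intervention")
  expect_lt(out_d$total_cost, out_0$total_cost)
  expect_lt(out_d$total_qalys, out_0$total_qalys)
})

test_that("arm totals equal the sum of the cost breakdown and scale linearly", {
  out <- run_arm(cfg, "intervention")
  expect_equal(out$total_cost, sum(out$cost_breakdown), tolerance = 1e-9)
  # doubling every unit cost doubles total cost exactly
  dbl <- cfg
  for (d in names(dbl$drugs))
    dbl$drugs[[d]]$price_per_vial <- 2 * dbl$drugs[[d]]$price_per_vial
  for (nm in names(dbl$admin)) dbl$admin[[nm]] <- 2 * dbl$admin[[nm]]
  for (nm in names(dbl$labs)) dbl$labs[[nm]] <- 2 * dbl$labs[[nm]]
  dbl$imaging$ct <- 2 * dbl$imaging$ct
  for (nm in names(dbl$ae$costs)) dbl$ae$costs[[nm]] <- 2 * dbl$ae$costs[[nm]]
  dbl$terminal$bsc_per_cycle <- 2 * dbl$terminal$bsc_per_cycle
  dbl$terminal$eol_once <- 2 * dbl$terminal$eol_once
  out2 <- run_arm(dbl, "intervention")
  expect_equal(out2$total_cost, 2 * out$total_cost, tolerance = 1e-9)
})

test_that("identical curves in both arms isolate the regimen cost difference", {
  cfg_same <- cfg
  cfg_same$survival$os$comparator <- cfg_same$survival$os$intervention
  cfg_same$survival$pfs$comparator <- cfg_same$survival$pfs$intervention
  oi <- run_arm(cfg_same, "intervention")
  oc <- run_arm(cfg_same, "comparator")
  # QALY difference comes only from the AE disutility gap
  ae_gap <- ae_burden(cfg_same, "comparator")$qaly_loss -
    ae_burden(cfg_same, "intervention")$qaly_loss
  expect_equal(oi$total_qalys - oc$total_qalys, ae_gap, tolerance = 1e-12)
  # cost difference: drug regimen + AE cost gap only
  tr <- build_trace(llogis_os_int(), llogis_pfs_int(), cfg_same$settings)
  disc <- discount_factor(tr$cycle, cfg_same$settings)
  drug_gap <- sum(disc * tr$pf *
                    (drug_cost_per_cycle(cfg_same, "intervention", tr$cycle) -
                       drug_cost_per_cycle(cfg_same, "comparator", tr$cycle)))
  ae_cost_gap <- ae_burden(cfg_same, "intervention")$cost -
    ae_burden(cfg_same, "comparator")$cost
  expect_equal(oi$total_cost - oc$total_cost, drug_gap + ae_cost_gap,
               tolerance = 1e-8)
})
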