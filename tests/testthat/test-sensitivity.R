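cfg <- default_config()

test_that("gamma moment matching reproduces mean and bounds-derived sd", {
  g <- gamma_from_mean_bounds(100, 60.8, 139.2)
  expect_equal(g$shape, 25, tolerance = 1e-12)
  expect_equal(g$scale, 4, tolerance = 1e-12)
  set.seed(2)
  for (i in 1:10) {
    m <- stats::runif(1, 1, 1000)
    g <- gamma_from_mean_bounds(m, 0.8 * m, 1.2 * m)
    expect_equal(g$shape * g$scale, m, tolerance = 1e-10)
  }
  expect_error(gamma_from_mean_bounds(10, 12, 15), "bounds")
  # Monte-Carlo: sample mean of pembrolizumab price within 0.5%
  g <- gamma_from_mean_bounds(2457.99, 1966.39, 2949.59)
  set.seed(10)
  x <- stats::rgamma(1e6, shape = g$shape, scale = g$scale)
  expect_lt(abs(mean(x) - 2457.99) / 2457.99, 0.005)
})

test_that("beta moment matching reproduces the utility distribution", {
  b <- beta_from_mean_bounds(0.76, 0.61, 0.91)
  # moment-matched parameters, computed independently
  expect_equal(b$alpha, 22.908353706666667, tolerance = 1e-9)
  expect_equal(b$beta, 7.23421696, tolerance = 1e-9)
  set.seed(11)
  x <- stats::rbeta(1e6, b$alpha, b$beta)
  expect_true(all(x > 0 & x < 1))
  expect_lt(abs(mean(x) - 0.76), 0.005)
  expect_error(beta_from_mean_bounds(0.5, 0, 1, divisor = 1.5), "infeasible")
  expect_error(beta_from_mean_bounds(1.2, 0.9, 1.4), "mean")
})

test_that("the sensitivity parameter set covers every bounded input once", {
  pars <- sensitivity_parameters(cfg)
  expect_equal(anyDuplicated(pars$path), 0)
  # 4 drugs + 3 admin + 6 labs + imaging + 12 AE costs + 24 AE risks +
  # 2 terminal + 3 utilities + discount
  expect_equal(nrow(pars), 56)
  expect_equal(pars$lower[pars$path == "settings.discount_annual"], 0)
  expect_equal(pars$upper[pars$path == "settings.discount_annual"], 0.08)
  reg <- pars[pars$dist == "gamma", ]
  expect_equal(reg$lower, 0.8 * reg$base, tolerance = 1e-12)
  expect_equal(reg$upper, 1.2 * reg$base, tolerance = 1e-12)
})

test_that("one-way analysis perturbs one parameter at a time", {
  scfg <- short_config(15)
  pars <- sensitivity_parameters(scfg)
  pick <- pars[pars$path %in% c("drugs.pembrolizumab.price_per_vial",
                                "utilities.pf",
                                "labs.urinalysis",
                                "ae.costs.hypertension"), ]
  dsa <- one_way_dsa(scfg, pick)
  expect_equal(nrow(dsa), 4)
  expect_true(all(diff(dsa$spread) <= 0))
  # a parameter with negligible influence has (near) zero spread, a major
  # cost driver a large one
  expect_lt(dsa$spread[dsa$parameter == "ae.costs.hypertension"], 1)
  expect_gt(dsa$spread[dsa$parameter == "drugs.pembrolizumab.price_per_vial"],
            dsa$spread[dsa$parameter == "labs.urinalysis"])
  # a +/-0% "perturbation" reproduces the base-case ICER exactly
  base_icer <- run_base_case(scfg)$icer
  degenerate <- pick[1, ]
  degenerate$lower <- degenerate$base
  degenerate$upper <- degenerate$base
  flat <- one_way_dsa(scfg, degenerate)
  expect_equal(flat$icer_at_lower, base_icer)
  expect_equal(flat$icer_at_upper, base_icer)
})

test_that("PSA is seed-deterministic and spans all parameters", {
  scfg <- short_config(10)
  a <- run_psa(scfg, n = 50, seed = 99)
  b <- run_psa(scfg, n = 50, seed = 99)
  expect_identical(a$draws, b$draws)
  c <- run_psa(scfg, n = 50, seed = 100)
  expect_false(identical(a$draws, c$draws))
  expect_equal(length(a$parameter_draws), 56)
})

test_that("PSA parameter draws match their configured means", {
  scfg <- short_config(5)
  psa <- run_psa(scfg, n = 3000, seed = 17)
  pars <- sensitivity_parameters(scfg)
  for (p in c("drugs.pembrolizumab.price_per_vial", "utilities.pf",
              "utilities.ae_disutility", "settings.discount_annual",
              "ae.risks.intervention.anemia")) {
    row <- pars[pars$path == p, ]
    x <- psa$parameter_draws[[p]]
    se <- stats::sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - row$base), 3 * se + 1e-12)
  }
})

test_that("the acceptability curve is the positive-NMB fraction and is monotone", {
  draws <- data.frame(delta_cost = c(10, 30), delta_qaly = c(1, 1))
  psa <- structure(list(draws = draws, wtp = 20, n = 2), class = "psa_result")
  cv <- ceac(psa, c(0, 20, 40))
  expect_equal(cv$probability, c(0, 0.5, 1))
  # all positive dQALY draws -> monotone non-decreasing curve
  set.seed(3)
  draws <- data.frame(delta_cost = stats::rnorm(500, 50, 40),
                      delta_qaly = stats::runif(500, 0.1, 2))
  psa$draws <- draws
  cv <- ceac(psa, seq(0, 500, by = 10))
  expect_true(all(diff(cv$probability) >= 0))
  # wtp = 0 counts cost-saving draws
  expect_equal(ceac(psa, 0)$probability, mean(draws$delta_cost < 0))
})
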