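test_that("simulation is deterministic under a fixed seed", {
  spec <- llogis_os_int()
  a <- simulate_ipd(spec, 500, censoring = "uniform", c_max = 60, seed = 11)
  b <- simulate_ipd(spec, 500, censoring = "uniform", c_max = 60, seed = 11)
  expect_identical(a, b)
  c <- simulate_ipd(spec, 500, censoring = "uniform", c_max = 60, seed = 12)
  expect_false(identical(a$time, c$time))
})

test_that("uncensored draws reproduce the analytic median and survivor", {
  spec <- llogis_os_int()
  ipd <- simulate_ipd(spec, 10000, censoring = "none", seed = 3)
  expect_true(all(ipd$event == 1))
  expect_lt(abs(stats::median(ipd$time) - 24.217), 1.0)
  # empirical survivor vs analytic, sup-norm over a grid
  grid <- seq(0.5, 80, by = 0.5)
  emp <- vapply(grid, function(g) mean(ipd$time > g), numeric(1))
  expect_lt(max(abs(emp - survival_prob(spec, grid))), 0.02)
})

test_that("near-zero administrative censoring censors everyone", {
  ipd <- simulate_ipd(llogis_os_int(), 200, censoring = "administrative",
                      t_admin = 0.001, seed = 5)
  expect_true(all(ipd$event == 0))
  expect_true(all(ipd$time == 0.001 | ipd$event == 1))
})

test_that("KM estimator matches hand-computed product-limit values", {
  ipd <- data.frame(time = c(1, 2, 3), event = c(1, 1, 1))
  class(ipd) <- c("pseudo_ipd", "data.frame")
  km <- km_estimate(ipd)
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3, 2, 1))
  # all censored -> survivor stays at 1
  cen <- data.frame(time = c(1, 2), event = c(0, 0))
  expect_true(all(km_estimate(cen)$survival == 1))
  # with censoring: times 1(event), 2(censored), 3(event) ->
  # S = 2/3, then unchanged at the censoring, then 2/3 * (1 - 1/1) = 0
  mix <- data.frame(time = c(1, 2, 3), event = c(1, 0, 1))
  expect_equal(km_estimate(mix)$survival, c(2 / 3, 2 / 3, 0))
})

test_that("KM on uncensored data equals the empirical survivor and hits 0.5 near the median", {
  spec <- llogis_pfs_int()
  ipd <- simulate_ipd(spec, 5000, censoring = "none", seed = 8)
  km <- km_estimate(ipd)
  at_med <- km$survival[findInterval(spec$scale, km$time)]
  expect_lt(abs(at_med - 0.5), 0.02)
  srt <- sort(ipd$time)
  expect_equal(km$survival, 1 - seq_along(srt) / length(srt),
               tolerance = 1e-12)
})

test_that("pseudo-IPD round-trips through CSV", {
  ipd <- simulate_ipd(llogis_os_comp(), 50, censoring = "uniform",
                      c_max = 40, seed = 2, arm_label = "comparator")
  path <- withr::local_tempfile(fileext = ".csv")
  write_ipd(ipd, path)
  back <- read_ipd(path)
  expect_equal(back$time, ipd$time)
  expect_equal(back$event, ipd$event)
})

test_that("recovery experiment summarizes bias and selection over replicates", {
  spec <- surv_spec("exponential", rate = 0.15)
  out <- recovery_experiment(spec, n = 400, reps = 5, seed = 21,
                             families = c("exponential", "weibull"))
  expect_equal(dim(out$estimates), c(5, 1))
  expect_lt(abs(out$bias[["rate"]]) / 0.15, 0.10)
  expect_true(out$selection_frequency >= 0 && out$selection_frequency <= 1)
  # reps = 1 equals that single replicate
  one <- recovery_experiment(spec, n = 400, reps = 1, seed = 21,
                             families = "exponential")
  expect_equal(unname(one$bias[["rate"]]),
               unname(one$estimates[1, "rate"] - 0.15))
})
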