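# shared fixtures: base-case curves and a coarse random spec generator

llogis_os_int <- function() surv_spec("log-logistic", scale = 24.217, shape = 1.546)
llogis_os_comp <- function() surv_spec("log-logistic", scale = 17.255, shape = 1.718)
llogis_pfs_int <- function() surv_spec("log-logistic", scale = 12.2045, shape = 1.4758)
llogis_pfs_comp <- function() surv_spec("log-logistic", scale = 8.1898, shape = 1.7748)

random_spec <- function(family) {
  if (family == "exponential") {
    surv_spec(family, rate = stats::runif(1, 0.01, 0.5))
  } else if (family == "gompertz") {
    surv_spec(family, shape = stats::runif(1, 0.01, 0.3),
              rate = stats::runif(1, 0.01, 0.2))
  } else {
    surv_spec(family, scale = stats::runif(1, 5, 40),
              shape = stats::runif(1, 0.8, 3))
  }
}

# config shrunk to a short horizon for fast model-structure tests
short_config <- function(n_cycles = 10) {
  cfg <- default_config()
  cfg$settings$n_cycles <- n_cycles
  cfg
}
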