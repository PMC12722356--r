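test_that("aggregation reproduces the printed mean/max/min table", {
  s <- aggregate_sources(source_table())
  get <- function(p, col) s[[col]][s$parameter == p]

  ## printed means, compared at the table's displayed precision (one unit
  ## in the last printed digit, which also covers truncated rounding)
  printed <- c(R_T = 2.4e4, kappa = 6.05e-5, S_T = 5.25e5, phi = 0.535,
               b = 0.035, gamma = 2.93e-4, alpha = 1.5e-4, beta = 0.503)
  ulp <- c(R_T = 0.1e4, kappa = 0.01e-5, S_T = 0.01e5, phi = 0.001,
           b = 0.001, gamma = 0.01e-4, alpha = 0.1e-4, beta = 0.001)
  for (p in names(printed)) {
    expect_lt(abs(get(p, "mean") - printed[[p]]), ulp[[p]] + 1e-12)
  }
  ## exact means where the printed value is exact
  expect_identical(get("phi", "mean"), 0.535)
  expect_identical(get("b", "mean"), 0.035)
  expect_identical(get("beta", "mean"), 0.503)
  expect_identical(get("S_T", "mean"), 5.25e5)

  ## full-precision mean for R_T is kept, not the rounded display value
  expect_equal(get("R_T", "mean"), 9.5708e4 / 4)

  ## extrema and source counts (gamma has 3 sources, alpha/beta have 2)
  expect_identical(get("gamma", "n_sources"), 3L)
  expect_identical(get("alpha", "n_sources"), 2L)
  expect_identical(get("beta", "n_sources"), 2L)
  expect_true(all(s$min <= s$mean & s$mean <= s$max))
  expect_identical(get("kappa", "max"), 1e-4)
  expect_identical(get("kappa", "min"), 1e-5)
})

test_that("aggregation handles single-source and missing rows", {
  tab <- tibble::tibble(source = "s1", parameter = "phi", value = 0.7)
  s <- aggregate_sources(tab)
  expect_equal(unlist(s[s$parameter == "phi", c("mean", "max", "min")]),
               c(mean = 0.7, max = 0.7, min = 0.7))
  bad <- tibble::tibble(source = "s1", parameter = "phi", value = NA_real_)
  expect_error(aggregate_sources(bad), "phi")
  neg <- tibble::tibble(source = "s1", parameter = "phi", value = -1)
  expect_error(aggregate_sources(neg), "phi")
})

test_that("the shipped CSV fixture matches the built-in table", {
  csv <- utils::read.csv(source_table_path(), stringsAsFactors = FALSE)
  expect_equal(tibble::as_tibble(csv), source_table())
})

test_that("parameter sets resolve selectors, derive v, and log overrides", {
  p <- mean_params(tau = 1)
  expect_equal(p$v, 1)
  expect_equal(p$phi, 0.535)
  expect_equal(p$v * p$tau, 1, tolerance = 1e-12)

  pmin <- parameter_set(mean_summary, "min", L_T = 10, tau = 4)
  for (f in c("R_T", "kappa", "S_T", "phi", "b", "gamma", "alpha", "beta")) {
    expect_identical(pmin[[f]], mean_summary$min[mean_summary$parameter == f])
  }

  po <- mean_params(overrides = list(phi = 0.8))
  expect_equal(po$phi, 0.8)
  expect_identical(po$overrides, list(phi = 0.8))
  base <- mean_params()
  for (f in c("R_T", "kappa", "S_T", "b", "gamma", "alpha", "beta")) {
    expect_identical(po[[f]], base[[f]])
  }
  ## constants can be overridden through the same mechanism
  pc <- mean_params(overrides = list(xi = 0.5))
  expect_equal(pc$constants$xi, 0.5)

  expect_error(mean_params(overrides = list(nope = 1)), "nope")
  expect_error(parameter_set(mean_summary, "mean", L_T = -1, tau = 1))
  expect_error(parameter_set(mean_summary, "mean", L_T = 1, tau = 0))
  expect_error(parameter_set(mean_summary, "typo"))
})

test_that("parameter_set is pure and serializes through YAML", {
  a <- mean_params(L_T = 123, tau = 3.3, N = 4)
  b <- mean_params(L_T = 123, tau = 3.3, N = 4)
  expect_identical(a, b)

  path <- withr::local_tempfile(fileext = ".yaml")
  write_parameter_set(a, path)
  back <- read_parameter_set(path)
  for (f in c("R_T", "kappa", "S_T", "phi", "b", "gamma", "alpha", "beta",
              "L_T", "tau", "v", "N")) {
    expect_equal(back[[f]], a[[f]], tolerance = 1e-9)
  }
  expect_equal(unclass(back$constants), unclass(a$constants))
})

test_that("model constants validate positivity and default eta to xi", {
  cn <- model_constants()
  expect_equal(cn$xi, 0.09)
  expect_equal(cn$Omega, 0.001)
  expect_equal(cn$r_off, 1.5)
  expect_equal(cn$r_phos, 1.03)
  expect_equal(cn$eta, cn$xi)
  cn2 <- model_constants(xi = 0.2)
  expect_equal(cn2$eta, 0.2)
  expect_error(model_constants(Omega = -1), "Omega")
})
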