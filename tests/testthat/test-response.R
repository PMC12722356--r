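test_that("the binding quadratic has the right limits and residual", {
  expect_equal(total_complex(1e3, 2e4, 0), 1e3)
  expect_equal(total_complex(5e4, 2e4, 0), 2e4)
  ## saturation limit: huge dose fills the receptor pool
  expect_equal(total_complex(1e12, 2e4, 5e3), 2e4, tolerance = 1e-6)
  ## residual oracle on a typical point
  p <- mean_params(L_T = 1e3, tau = 1)
  K_D <- p$v / p$kappa
  C_T <- total_complex(p$L_T, p$R_T, K_D)
  expect_equal(p$kappa * (p$L_T - C_T) * (p$R_T - C_T), p$v * C_T,
               tolerance = 1e-9 * p$v * C_T)
  ## vectorised over dose and monotone in dose
  ct <- total_complex(10^(0:6), p$R_T, K_D)
  expect_length(ct, 7)
  expect_true(all(diff(ct) > 0))
})

test_that("closed forms match ODE steady states for the fully specified models", {
  p <- mean_params()
  Ls <- 10^seq(0, 6, length.out = 5)
  taus <- 10^seq(-0.5, 1.2, length.out = 4)
  for (id in c(1, 2, 3, 4, 9)) {
    for (tv in taus) {
      an <- analytic_response(id, p, L_T = Ls, tau = tv)
      nu <- numeric_response(id, p, L_T = Ls, tau = tv)
      expect_equal(nu, an, tolerance = 1e-6)
    }
  }
})

test_that("aux-based closed forms match the ODE for models 5-8", {
  p <- mean_params()
  for (id in 5:8) {
    for (pt in list(c(1e2, 2), c(1e3, 5), c(1e4, 1))) {
      an <- analytic_response(id, p, L_T = pt[1], tau = pt[2])
      nu <- numeric_response(id, p, L_T = pt[1], tau = pt[2])
      expect_equal(nu, an, tolerance = 1e-6)
    }
  }
})

test_that("analytic/numeric agreement holds across random parameter sets", {
  rows <- fuzz_scenarios(8, seed = 21)
  for (i in seq_len(nrow(rows))) {
    params <- scenario_params(rows[i, ])
    id <- rows$id[i]
    an <- analytic_response(id, params)
    nu <- numeric_response(id, params)
    expect_equal(nu, an, tolerance = 1e-5)
  }
})

test_that("degenerate inputs behave as limits dictate", {
  p <- mean_params()
  expect_equal(analytic_response(2, p, L_T = 0), 0)
  expect_equal(analytic_response(7, p, L_T = 0),
               p$constants$l_total * p$constants$iff_c /
                 (p$constants$iff_c + p$constants$iff_d))
  ## limited signalling with xi -> 0 collapses onto plain KPR
  p0 <- mean_params(overrides = list(xi = 1e-300))
  grid <- 10^seq(0, 6, length.out = 10)
  expect_equal(analytic_response(3, p0, L_T = grid),
               analytic_response(2, p0, L_T = grid))
})

test_that("E_max and EC_50 match their closed forms", {
  p <- mean_params(tau = 2)
  K_D <- p$v / p$kappa
  a <- p$phi / (p$phi + p$v)

  m1 <- emax_ec50(1, p)
  expect_equal(m1$E_max, p$R_T, tolerance = 1e-3)
  expect_equal(m1$EC_50, K_D + p$R_T / 2, tolerance = 5e-3)

  m2 <- emax_ec50(2, p)
  expect_equal(m2$E_max, a^p$N * p$R_T, tolerance = 1e-3)
  expect_equal(m2$EC_50, K_D + p$R_T / 2, tolerance = 5e-3)

  m3 <- emax_ec50(3, p)
  expect_equal(m3$E_max, (p$v / (p$v + p$constants$xi)) * a^p$N * p$R_T,
               tolerance = 1e-3)
  expect_equal(m3$EC_50, analytic_ec50(3, p), tolerance = 5e-3)

  ## sustained signalling: E_max = R_T independent of tau
  for (tv in c(0.5, 2, 10)) {
    m4 <- emax_ec50(4, p, tau = tv)
    expect_equal(m4$E_max, p$R_T, tolerance = 1e-2)
  }

  ## the bell-shaped negative-feedback curve records its branch
  m5 <- emax_ec50(5, p, grid = dose_grid(120))
  expect_match(m5$branch, "bell")
})

test_that("numeric EC_50 falls with dissociation time via K_D", {
  p <- mean_params()
  for (id in 1:3) {
    ecs <- vapply(c(0.5, 2, 10), function(tv) {
      emax_ec50(id, p, tau = tv)$EC_50
    }, numeric(1))
    expect_true(all(diff(ecs) < 0))
  }
})

test_that("response curves are tidy, deterministic and shape-correct", {
  p <- mean_params()
  cv <- response_curve(3, p, axis = "tau", grid = tau_grid(40), at = 1e3)
  expect_s3_class(cv, "tcell_curve")
  expect_identical(nrow(cv), 40L)
  expect_true(all(cv$response >= 0))
  expect_true(all(is.finite(cv$response)))
  cv2 <- response_curve(3, p, axis = "tau", grid = tau_grid(40), at = 1e3)
  expect_identical(cv$response, cv2$response)

  ## KPR response never decreases with dissociation time
  cv_kpr <- response_curve(2, p, axis = "tau", grid = tau_grid(30), at = 1e3)
  expect_true(all(diff(cv_kpr$response) > -1e-9))

  ## negative-feedback dose curve rises then decays (bell)
  cv5 <- response_curve(5, p, axis = "dose",
                        grid = dose_grid(40, 1e0, 1e6), at = 2)
  imax <- which.max(cv5$response)
  expect_gt(imax, 1)
  expect_lt(imax, 40)
  expect_lt(cv5$response[40], 0.1 * max(cv5$response))

  ## a single-point grid yields a single-value curve
  one <- response_curve(2, p, axis = "dose", grid = 1e3)
  expect_identical(nrow(one), 1L)
  expect_equal(one$response, analytic_response(2, p, L_T = 1e3),
               tolerance = 1e-6)
})

test_that("the model-5 auxiliaries are consistent", {
  params <- parameter_set(mean_summary, "mean", L_T = 100, tau = 20, N = 5,
                          overrides = list(phi = 1))
  aux <- analytic_aux(5, params)
  expect_length(aux$S_roots, 3)
  expect_equal(aux$S_ss, min(aux$S_roots))
  ## recurrence roots bracket correctly and collapse to a when lam -> 0
  expect_lt(aux$r_minus, aux$r_plus)
  rr0 <- tcellkpr:::nf_recurrence_roots(0.5, 0.5, 0)
  expect_equal(rr0[["r_minus"]], 0.5)
})

test_that("kinetic proofreading specificity follows exponential survival", {
  expect_equal(specificity_ratio(5, 5, 1), exp(4))
  expect_identical(round(specificity_ratio()), 55)
  expect_equal(specificity_ratio(), 54.598, tolerance = 1e-4)
})
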