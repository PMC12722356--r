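test_that("occupancy binding rises monotonically to the quadratic root", {
  p <- mean_params(L_T = 1e3, tau = 2)
  m <- build_model(1, p)
  tr <- simulate_model(m, t_end = 2e3, n_out = 100)
  C <- tr$states[, "C0"]
  expect_true(all(diff(C) >= -1e-6 * max(C)))
  C_T <- total_complex(p$L_T, p$R_T, p$v / p$kappa)
  expect_equal(C[length(C)], C_T, tolerance = 1e-7)
  ## the root satisfies the mass-action balance
  expect_equal(p$kappa * (p$L_T - C_T) * (p$R_T - C_T), p$v * C_T,
               tolerance = 1e-9)
})

test_that("a trajectory started at a steady state stays put", {
  p <- mean_params(N = 3)
  m <- build_model(3, p)
  ss <- find_steady_states(m, n_starts = 30, seed = 2)
  expect_identical(nrow(ss), 1L)
  tr <- simulate_model(m, init = ss$state[[1]], t_end = 1e3, n_out = 10)
  drift <- apply(tr$states, 1, function(s) max(abs(s - ss$state[[1]])))
  expect_lt(max(drift) / max(ss$state[[1]]), 1e-6)
})

test_that("the chain total solves the scalar binding equation in time", {
  p <- mean_params(L_T = 800, tau = 1.2, N = 4)
  m <- build_model(3, p)
  times <- seq(0, 200, length.out = 40)
  S1 <- rowSums(simulate_model(m, times = times)$states[, paste0("C", 0:5)])
  scalar <- deSolve::ode(
    y = c(S = 0), times = times,
    func = function(t, y, parms) {
      list(p$kappa * (p$L_T - y) * (p$R_T - y) - p$v * y)
    }, parms = NULL, rtol = 1e-10, atol = 1e-12)
  expect_equal(S1, unname(scalar[, 2]), tolerance = 1e-7)
})

test_that("monostable models have a unique interior steady state", {
  p <- mean_params(L_T = 1e3, tau = 2)
  for (id in c(1, 2, 4, 6)) {
    ss <- find_steady_states(build_model(id, p), n_starts = 60, seed = 3)
    expect_identical(nrow(ss), 1L)
    expect_true(ss$interior)
    expect_lt(ss$residual, 1e-8 * p$R_T)
    expect_identical(ss$stability, "stable")
  }
  ## the occupancy steady state equals the closed-form total complex
  ss1 <- find_steady_states(build_model(1, p), n_starts = 20, seed = 3)
  expect_equal(ss1$readout, total_complex(p$L_T, p$R_T, p$v / p$kappa),
               tolerance = 1e-8)
})

test_that("the negative-feedback model is tristable at the located point", {
  params <- parameter_set(mean_summary, "mean", L_T = 100, tau = 20, N = 5,
                          overrides = list(phi = 1))
  ss <- find_steady_states(build_model(5, params), n_starts = 200, seed = 1)
  expect_identical(nrow(ss), 3L)
  expect_true(all(ss$interior))
  expect_identical(sum(ss$stability == "stable"), 2L)
  expect_identical(sum(ss$stability == "unstable"), 1L)
  ## cross-check the count against the scalar SHP-1 balance, an
  ## independent reduction of the steady-state problem
  aux <- analytic_aux(5, params)
  expect_length(aux$S_roots, 3)
  S_found <- sort(vapply(ss$state, function(s) s[["S"]], numeric(1)))
  expect_equal(S_found, sort(aux$S_roots), tolerance = 1e-4)
})

test_that("stability classification flags stable, unstable and marginal", {
  p <- mean_params()
  m1 <- build_model(1, p)
  ss <- find_steady_states(m1, n_starts = 10, seed = 1)
  st <- classify_stability(m1, ss$state[[1]])
  expect_identical(st$stability, "stable")
  expect_true(all(Re(st$eigenvalues) < 0))

  ## a rate below the threshold produces a numerically marginal direction
  marg <- build_model(1, p)
  marg$reactions[[2]]$rate <- 1e-15
  marg$reactions[[1]]$rate <- 1e-15
  marg$compiled <- tcellkpr:::compile_network(marg$species, marg$reactions)
  st2 <- classify_stability(marg, c(L = p$L_T, R = p$R_T, C0 = 0))
  expect_identical(st2$stability, "marginal")
})

test_that("a degenerate scan grid yields a single annotated row", {
  sc <- scan_multistability(phi_grid = 0.6, tau_grid = 2, L_T_grid = 1e3,
                            n_starts = 30, seed = 5)
  expect_identical(nrow(sc), 1L)
  expect_identical(sc$n_states, 1L)
  expect_identical(sc$n_stable, 1L)
})
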