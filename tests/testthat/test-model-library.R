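test_that("the limited-signalling chain reproduces its printed equations", {
  p <- mean_params(L_T = 1e3, tau = 2, N = 2)
  m <- build_model(3, p)
  expect_setequal(m$species, c("L", "R", "C0", "C1", "C2", "C3"))

  set.seed(7)
  for (k in 1:10) {
    C <- runif(4, 0, 100)
    S1 <- sum(C)
    x <- c(L = p$L_T - S1, R = p$R_T - S1, C0 = C[1], C1 = C[2],
           C2 = C[3], C3 = C[4])
    d <- model_rhs(m, x)
    xi <- p$constants$xi
    expect_equal(d[["C0"]],
                 p$kappa * (p$L_T - S1) * (p$R_T - S1) - (p$phi + p$v) * C[1])
    expect_equal(d[["C1"]], p$phi * C[1] - (p$phi + p$v) * C[2])
    expect_equal(d[["C2"]], p$phi * C[2] - (p$v + xi) * C[3])
    expect_equal(d[["C3"]], xi * C[3] - p$v * C[4])
    ## the chain total obeys the scalar binding equation
    expect_equal(sum(d[c("C0", "C1", "C2", "C3")]),
                 p$kappa * (p$L_T - S1) * (p$R_T - S1) - p$v * S1)
  }

  ## at the origin only C0 is produced
  d0 <- model_rhs(m, m$init)
  expect_equal(d0[["C0"]], p$kappa * p$L_T * p$R_T)
  expect_equal(unname(d0[c("C1", "C2", "C3")]), c(0, 0, 0))
})

test_that("the occupancy model is the one-step specialization", {
  p <- mean_params()
  m <- build_model(1, p)
  x <- c(L = p$L_T - 50, R = p$R_T - 50, C0 = 50)
  d <- model_rhs(m, x)
  expect_equal(d[["C0"]],
               p$kappa * (p$L_T - 50) * (p$R_T - 50) - p$v * 50)
})

test_that("generated Jacobians match finite differences", {
  p <- mean_params(N = 3)
  for (id in c(3, 5, 8)) {
    m <- build_model(id, p)
    set.seed(id)
    x <- runif(length(m$species), 1, 50)
    J <- model_jacobian(m, stats::setNames(x, m$species))
    h <- 1e-6
    Jfd <- sapply(seq_along(x), function(j) {
      xp <- x; xp[j] <- xp[j] + h
      xm <- x; xm[j] <- xm[j] - h
      (network_rhs_for_test(m, xp) - network_rhs_for_test(m, xm)) / (2 * h)
    })
    expect_equal(unname(J), unname(Jfd), tolerance = 1e-5)
  }
})

test_that("model-relation limits hold as trajectory equivalences", {
  p0 <- mean_params(L_T = 500, tau = 1.5, N = 3)
  times <- seq(0, 50, length.out = 21)
  run <- function(m) simulate_model(m, times = times)$states

  ## xi = 0 turns model 3 into model 2 on the shared chain
  p_xi0 <- mean_params(L_T = 500, tau = 1.5, N = 3,
                       overrides = list(xi = 1e-300))
  s3 <- run(build_model(3, p_xi0))
  s2 <- run(build_model(2, p0))
  for (sp in c("L", "R", "C0", "C1", "C2", "C3")) {
    expect_equal(s3[, sp], s2[, sp], tolerance = 1e-7)
  }

  ## r_off = r_phos = 1 turns the stabilizing chain into plain KPR
  p_r1 <- mean_params(L_T = 500, tau = 1.5, N = 3,
                      overrides = list(r_off = 1, r_phos = 1))
  s6 <- run(build_model(6, p_r1))
  expect_equal(s6, s2, tolerance = 1e-7)

  ## xi = 0 turns model 9 into model 4 (the xi branch decouples)
  s9 <- run(build_model(9, p_xi0))
  s4 <- run(build_model(4, p0))
  for (sp in colnames(s4)) {
    expect_equal(s9[, sp], s4[, sp], tolerance = 1e-7)
  }

  ## removing the feedback (gamma = 0, alpha = 0, b = 0) reduces the
  ## negative-feedback chain to plain KPR
  p_nf <- mean_params(L_T = 500, tau = 1.5, N = 3,
                      overrides = list(gamma = 0, alpha = 0, b = 0))
  m5 <- build_model(5, p_nf)
  x2 <- c(L = 400, R = 2e4, C0 = 40, C1 = 30, C2 = 20, C3 = 10)
  x5 <- c(x2, S = 0, Si = p_nf$S_T)
  d5 <- model_rhs(m5, x5)
  d2 <- model_rhs(build_model(2, p0), x2)
  expect_equal(d5[names(d2)], d2)

  ## model 7 is the xi -> 0 limit of model 8 (steady-state responses)
  p5 <- mean_params(L_T = 1e3, tau = 2, N = 5)
  r7 <- numeric_response(7, p5)
  r8lim <- numeric_response(8, mean_params(L_T = 1e3, tau = 2, N = 5,
                                           overrides = list(xi = 1e-9)))
  expect_equal(r8lim, r7, tolerance = 1e-5)
})

test_that("conservation and nonnegativity hold along trajectories", {
  rows <- fuzz_scenarios(6, seed = 11)
  for (i in seq_len(nrow(rows))) {
    params <- scenario_params(rows[i, ])
    id <- rows$id[i]
    m <- build_model(id, params)
    tr <- simulate_model(m, t_end = 500, n_out = 30)
    expect_gte(min(tr$states), -1e-6)
    cons <- apply(tr$states, 1, function(s) conserved_quantities(m, s))
    for (j in seq_len(nrow(cons))) {
      expect_equal(max(abs(cons[j, ] / cons[j, 1] - 1)), 0, tolerance = 1e-8)
    }
  }
})

test_that("reduction eliminates one unknown per conserved quantity", {
  p <- mean_params(N = 2)
  m3 <- build_model(3, p)
  red <- reduce_by_conservation(m3)
  expect_length(red$kept, 4)  # 6 species - 2 conserved quantities

  m1 <- build_model(1, p)
  expect_length(reduce_by_conservation(m1)$kept, 1)

  ## round trip reduced -> full -> reduced is the identity, and the
  ## reduced rhs matches the full rhs on kept species
  xr <- c(10, 5, 2, 1)
  full <- red$to_full(xr)
  expect_equal(unname(full[red$kept]), xr)
  expect_equal(unname(red$rhs(xr)),
               unname(model_rhs(m3, full)[red$kept]))
  expect_equal(conserved_quantities(m3, full),
               c(L_T = p$L_T, R_T = p$R_T))
  m3neg <- m3
  m3neg$conserved[[1]]$total <- -5
  expect_error(reduce_by_conservation(m3neg), "empty")
})

test_that("readouts and exports are wired per model", {
  p <- mean_params(N = 2)
  readouts <- list("1" = "C0", "2" = "C2", "3" = "C2", "4" = c("C2", "D"),
                   "5" = "C2", "6" = "C2", "7" = "X", "8" = "X",
                   "9" = c("C2", "D"))
  for (id in 1:9) {
    m <- build_model(id, p)
    expect_identical(names(m$readout), readouts[[as.character(id)]])
    lines <- reaction_lines(m)
    expect_length(lines, length(m$reactions))
    expect_true(all(grepl(" -> .* ; ", lines)))
    edges <- reaction_edges(m)
    expect_identical(nrow(edges), length(m$reactions))
  }
  expect_error(build_model(10, p), "unknown model id")
})
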