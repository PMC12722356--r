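## Response surfaces: analytic steady-state response expressions per model,
## numeric steady-state responses from the ODE systems, dose- and
## dissociation-time curves, and E_max / EC_50 extraction.

#' Equilibrium total bound complexes
#'
#' The smaller root of the binding quadratic
#' `kappa (L_T - C)(R_T - C) = v C`, i.e.
#' `C_T = (L_T + R_T + K_D - sqrt((L_T + R_T + K_D)^2 - 4 L_T R_T)) / 2`
#' with `K_D = v / kappa`.
#'
#' @param L_T Total ligand (vectorised), molecules/cell.
#' @param R_T Total receptor, molecules/cell.
#' @param K_D Dissociation constant `v / kappa`, molecules/cell.
#' @return `C_T`, molecules/cell.
#' @export
total_complex <- function(L_T, R_T, K_D) {
  stopifnot(all(L_T >= 0), R_T >= 0, all(K_D >= 0))
  s <- L_T + R_T + K_D
  disc <- s^2 - 4 * L_T * R_T
  if (any(disc < -1e-9 * s^2)) stop("negative discriminant in binding quadratic")
  disc[disc < 0] <- 0
  (s - sqrt(disc)) / 2
}

#' Binding quantities for a parameter set
#'
#' @param params A [parameter_set()].
#' @param L_T,tau Optional overrides of the set's dose and dissociation
#'   time.
#' @return A list with `K_D`, `C_T`, `a` (the proofreading pass factor
#'   `phi / (phi + v)`), and `L_free = L_T - C_T`.
#' @export
binding_quantities <- function(params, L_T = params$L_T, tau = params$tau) {
  v <- 1 / tau
  K_D <- v / params$kappa
  C_T <- total_complex(L_T, params$R_T, K_D)
  list(K_D = K_D, C_T = C_T, a = params$phi / (params$phi + v),
       L_free = L_T - C_T)
}

## ---- model 5 / 6 auxiliaries -------------------------------------------

## Internal: normalized chain occupancy shares for the negative-feedback
## chain at feedback level S (protected first step): returns c_0..c_N with
## sum 1.
nf_chain_shape <- function(phi, v, b, gamma, S, N) {
  lam <- b + gamma * S  # dephosphorylation rate on steps j >= 2
  A <- matrix(0, N + 1, N + 1)
  ## balance of C_j for j = 1..N (the C_0 balance is replaced by the
  ## normalization; it is implied by the total binding balance)
  for (j in 1:N) {
    back_in <- if (j < N) (if (j + 1 >= 2) lam else b) else 0
    back_out <- if (j >= 2) lam else b
    A[j, j] <- phi                                   # inflow from C_{j-1}
    A[j, j + 1] <- -(v + back_out + (if (j < N) phi else 0))
    if (j < N) A[j, j + 2] <- back_in
  }
  A[N + 1, ] <- 1
  drop(solve(A, c(rep(0, N), 1)))
}

## Internal: SHP-1 balance g(S) = alpha C_1 (S_T - S) - beta S at total
## binding C_T; its roots are the steady-state S values.
nf_S_balance <- function(S, params, C_T) {
  sh <- nf_chain_shape(params$phi, params$v, params$b, params$gamma, S,
                       params$N)
  params$alpha * sh[2] * C_T * (params$S_T - S) - params$beta * S
}

## Internal: all steady-state S roots for model 5 at a given dose, by sign
## scanning on a log-spaced grid plus bisection.
nf_S_roots <- function(params, C_T, n_grid = 400) {
  Ss <- c(0, 10^seq(-3, log10(params$S_T), length.out = n_grid - 1))
  gv <- vapply(Ss, nf_S_balance, numeric(1), params = params, C_T = C_T)
  idx <- which(gv[-1] * gv[-length(gv)] < 0)
  vapply(idx, function(i) {
    stats::uniroot(nf_S_balance, c(Ss[i], Ss[i + 1]), params = params,
                   C_T = C_T, tol = 1e-10 * params$S_T)$root
  }, numeric(1))
}

## Internal: characteristic roots r+- of the interior negative-feedback
## recurrence lam r^2 - (phi + v + lam) r + phi = 0 (lam the total
## backward rate); r_minus -> a as lam -> 0.
nf_recurrence_roots <- function(phi, v, lam) {
  if (lam <= 0) return(c(r_minus = phi / (phi + v), r_plus = Inf))
  disc <- (phi + v + lam)^2 - 4 * lam * phi
  c(r_minus = ((phi + v + lam) - sqrt(disc)) / (2 * lam),
    r_plus = ((phi + v + lam) + sqrt(disc)) / (2 * lam))
}

## Internal: stabilizing-chain (model 6) composites: occupancy shares,
## effective unbinding rate and the response fraction delta_stab.
stab_chain_aux <- function(params) {
  N <- params$N
  cn <- params$constants
  v_i <- params$v * cn$r_off^(-(0:N))
  phi_i <- params$phi * cn$r_phos^(0:(N - 1))
  c_i <- numeric(N + 1)
  c_i[1] <- 1
  for (i in 1:N) {
    out <- v_i[i + 1] + (if (i < N) phi_i[i + 1] else 0)
    c_i[i + 1] <- c_i[i] * phi_i[i] / out
  }
  share <- c_i / sum(c_i)
  v_eff <- sum(v_i * share)
  list(delta_stab = share[N + 1], v_eff = v_eff,
       K_D_eff = v_eff / params$kappa)
}

## Internal: IFF output-layer steady state given the driving signalling
## state occupancy Z = C_N.
iff_output <- function(Z, constants) {
  cn <- constants
  Y <- cn$sigma_act * Z * cn$m_total / (cn$sigma_act * Z + cn$iff_a)
  X <- cn$l_total * (cn$iff_c + cn$delta_act * Y) /
    (cn$iff_c + cn$iff_d + cn$delta_act * Y + cn$mu_inh * Z)
  list(X = X, Y = Y)
}

#' Analytic steady-state auxiliaries for models 5-8
#'
#' The quantities entering the negative-feedback, stabilizing-chain and
#' feed-forward response expressions, computed from the models' own steady
#' states rather than from symbolic composite expressions.
#'
#' @param id Model id in 5:8.
#' @param params A [parameter_set()].
#' @param L_T,tau Optional dose / dissociation-time overrides.
#' @return A named list (contents depend on the model): `r_minus`,
#'   `r_plus`, `S_ss` and `lambda` for model 5; `delta_stab`, `v_eff`,
#'   `K_D_eff` for model 6; `Y_ss` and `Z` for models 7 and 8.
#' @export
analytic_aux <- function(id, params, L_T = params$L_T, tau = params$tau) {
  stopifnot(id %in% 5:8)
  params <- refresh_tau(params, tau)
  bq <- binding_quantities(params, L_T = L_T, tau = tau)
  if (id == 5) {
    roots <- nf_S_roots(params, bq$C_T)
    S <- if (length(roots)) min(roots) else 0
    lam <- params$b + params$gamma * S
    rr <- nf_recurrence_roots(params$phi, params$v, lam)
    list(S_ss = S, S_roots = roots, lambda = lam,
         r_minus = rr[["r_minus"]], r_plus = rr[["r_plus"]])
  } else if (id == 6) {
    stab_chain_aux(params)
  } else {
    v <- params$v
    Z <- if (id == 7) bq$a^params$N * bq$C_T
    else (v / (v + params$constants$xi)) * bq$a^params$N * bq$C_T
    out <- iff_output(Z, params$constants)
    list(Y_ss = out$Y, Z = Z)
  }
}

## Internal: a parameter set with tau (and v) replaced.
refresh_tau <- function(params, tau) {
  if (identical(tau, params$tau)) return(params)
  params$tau <- tau
  params$v <- 1 / tau
  params
}

#' Analytic steady-state response
#'
#' Evaluates the closed-form response expressions. Models 1-4 and 9 are
#' fully specified in terms of `C_T`, `a = phi/(phi+v)` and the model
#' constants (for models 4 and 9 the ligand entering the expressions is
#' the free ligand `L_T - C_T`). Models 5-8 use [analytic_aux()]
#' quantities computed from the models' own steady states.
#'
#' @param id Model id, 1..9.
#' @param params A [parameter_set()].
#' @param L_T,tau Optional dose / dissociation-time overrides
#'   (vectorised over `L_T`).
#' @return Response in readout counts per cell (same length as `L_T`).
#' @export
analytic_response <- function(id, params, L_T = params$L_T,
                              tau = params$tau) {
  stopifnot(id %in% 1:9)
  params <- refresh_tau(params, tau)
  v <- params$v
  N <- params$N
  cn <- params$constants
  bq <- binding_quantities(params, L_T = L_T, tau = tau)
  C_T <- bq$C_T
  a <- bq$a
  Lf <- bq$L_free
  kap <- params$kappa
  switch(as.character(id),
    "1" = C_T,
    "2" = a^N * C_T,
    "3" = (v / (v + cn$xi)) * a^N * C_T,
    "4" = (kap * Lf + v + cn$Omega) / (cn$Omega + a^N * kap * Lf) * a^N * C_T,
    "5" = vapply(seq_along(L_T), function(i) {
      aux <- analytic_aux(5, params, L_T = L_T[i], tau = tau)
      sh <- nf_chain_shape(params$phi, v, params$b, params$gamma,
                           aux$S_ss, N)
      sh[N + 1] * C_T[i]
    }, numeric(1)),
    "6" = {
      aux <- stab_chain_aux(params)
      aux$delta_stab * total_complex(L_T, params$R_T, aux$K_D_eff)
    },
    "7" = iff_output(a^N * C_T, cn)$X,
    "8" = iff_output((v / (v + cn$xi)) * a^N * C_T, cn)$X,
    "9" = v * (kap * Lf + cn$Omega + v) /
      (a^N * kap * Lf * v + cn$Omega * v + cn$xi * kap * Lf +
         cn$xi * cn$Omega) * a^N * C_T
  )
}

## ---- numeric responses -------------------------------------------------

## Internal: steady state of the reduced system by Newton from several
## deterministic starts, falling back to integration + polish. `warm` may
## supply a previous solution as the first start.
steady_state_reduced <- function(model, red = NULL, warm = NULL) {
  if (is.null(red)) red <- reduce_by_conservation(model)
  starts <- list()
  if (!is.null(warm)) starts <- c(starts, list(warm))
  starts <- c(starts, list(sample_start_center(red),
                           numeric(length(red$upper))))
  scale <- max(vapply(model$conserved, `[[`, numeric(1), "total"))
  for (x0 in starts) {
    x <- newton_root(red, x0)
    if (!is.null(x) && all(red$to_full(x) >= -1e-8 * scale)) return(x)
  }
  ## fall back: integrate from rest, then polish
  x <- integrate_to_steady(model, red = red)
  if (is.null(x)) stop("steady-state search failed for model ", model$id)
  x
}

## Internal: forward-integrate the full system from `init` until the
## right-hand side is small, then Newton-polish on the reduced system.
integrate_to_steady <- function(model, init = model$init, red = NULL,
                                t_max = 1e6) {
  if (is.null(red)) red <- reduce_by_conservation(model)
  scale <- max(vapply(model$conserved, `[[`, numeric(1), "total"))
  x <- as_model_state(model, init)
  t_end <- 1e3
  repeat {
    tr <- simulate_model(model, init = x, t_end = t_end, n_out = 5)
    x <- pmax(tr$states[nrow(tr$states), ], 0)
    xr <- x[match(red$kept, model$species)]
    pol <- newton_root(red, xr)
    ok <- !is.null(pol) && all(red$to_full(pol) >= -1e-8 * scale)
    ## accept early only if the polished root is close to where the
    ## trajectory currently sits (avoid jumping basins)
    if (ok && sqrt(sum((pol - xr)^2)) <=
          0.05 * max(1e-8 * scale, sqrt(sum(xr^2)))) {
      return(pol)
    }
    if (t_end >= t_max) return(if (ok) pol else NULL)
    t_end <- t_end * 10
  }
}

#' Numeric steady-state response
#'
#' The steady-state value of the model's designated readout, computed from
#' the ODE system. Monostable models use damped-Newton root finding on the
#' reduced system; model 5 (negative feedback, potentially multistable)
#' uses the state reached by forward integration from the resting, fully
#' unbound initial condition — the documented selection rule.
#'
#' @inheritParams analytic_response
#' @return Response (readout counts per cell), same length as `L_T`.
#' @export
numeric_response <- function(id, params, L_T = params$L_T,
                             tau = params$tau) {
  stopifnot(id %in% 1:9)
  out <- numeric(length(L_T))
  warm <- NULL
  for (i in seq_along(L_T)) {
    params_i <- refresh_tau(params, tau)
    params_i$L_T <- L_T[i]
    model <- build_model(id, params_i)
    red <- reduce_by_conservation(model)
    x <- if (id == 5) {
      integrate_to_steady(model, red = red)
    } else {
      steady_state_reduced(model, red = red, warm = warm)
    }
    if (is.null(x)) stop("steady-state search failed (model ", id,
                         ", L_T = ", L_T[i], ")")
    warm <- x
    out[i] <- model_readout(model, red$to_full(x))
  }
  out
}

## ---- curves and dose metrics -------------------------------------------

#' Default dose and dissociation-time grids
#'
#' 200 log-spaced doses over 1e-1..1e7 molecules/cell and 120 log-spaced
#' dissociation times over 1e-1..1e2 s; wide enough to bracket
#' `EC_50 = K_D + R_T/2` across the literature parameter ranges.
#'
#' @param n Number of grid points.
#' @param from,to Grid end points.
#' @return Numeric grid (strictly increasing).
#' @export
dose_grid <- function(n = 200, from = 1e-1, to = 1e7) {
  10^seq(log10(from), log10(to), length.out = n)
}

#' @rdname dose_grid
#' @export
tau_grid <- function(n = 120, from = 1e-1, to = 1e2) {
  10^seq(log10(from), log10(to), length.out = n)
}

#' Response curve along dose or dissociation time
#'
#' @param id Model id, 1..9.
#' @param params A [parameter_set()]; the non-swept axis is fixed at the
#'   set's value unless `at` is given.
#' @param axis `"dose"` (sweep `L_T`) or `"tau"` (sweep `tau`).
#' @param grid Grid for the swept axis; defaults to [dose_grid()] or
#'   [tau_grid()].
#' @param at Fixed value of the other axis (defaults to the parameter
#'   set's `tau` or `L_T`).
#' @param method `"numeric"` (ODE steady state) or `"analytic"`
#'   (closed form).
#' @return A tibble of class `tcell_curve` with columns `model`, `axis`,
#'   `x`, `response`, `method` and attributes `axis`, `at`, `params`.
#' @export
response_curve <- function(id, params = parameter_set(),
                           axis = c("dose", "tau"), grid = NULL, at = NULL,
                           method = c("numeric", "analytic")) {
  axis <- match.arg(axis)
  method <- match.arg(method)
  if (is.null(grid)) grid <- if (axis == "dose") dose_grid() else tau_grid()
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  f <- if (method == "numeric") numeric_response else analytic_response
  if (axis == "dose") {
    at <- at %||% params$tau
    y <- f(id, params, L_T = grid, tau = at)
  } else {
    at <- at %||% params$L_T
    y <- vapply(grid, function(tv) f(id, params, L_T = at, tau = tv),
                numeric(1))
  }
  out <- tibble::tibble(model = id, axis = axis, x = grid, response = y,
                        method = method)
  class(out) <- c("tcell_curve", class(out))
  attr(out, "axis") <- axis
  attr(out, "at") <- at
  attr(out, "params") <- params
  out
}

#' E_max and EC_50 of a dose-response curve
#'
#' `E_max` is the supremum of the response over the dose grid; `EC_50` is
#' the dose at half `E_max`, located on the rising branch by bisection to
#' a relative dose accuracy of 1e-4. For saturating curves the top of the
#' grid must be within 1% of the plateau, otherwise an error suggests
#' widening the grid; bell-shaped curves are handled by restricting to the
#' rising branch (recorded in the output).
#'
#' @param id Model id, 1..9.
#' @param params A [parameter_set()].
#' @param tau Dissociation time at which the dose curve is taken.
#' @param grid Dose grid (defaults to [dose_grid()]).
#' @param method `"numeric"` or `"analytic"`.
#' @param widen Automatically extend the top of the grid (decade by
#'   decade, up to `widen_cap`) until the saturation precondition holds;
#'   with `widen = FALSE` a non-saturating curve is an error.
#' @param widen_cap Upper dose bound for automatic widening.
#' @return A one-row tibble: `model`, `tau`, `E_max`, `EC_50`, `branch`,
#'   `method`.
#' @export
emax_ec50 <- function(id, params = parameter_set(), tau = params$tau,
                      grid = dose_grid(), method = c("numeric", "analytic"),
                      widen = TRUE, widen_cap = 1e12) {
  method <- match.arg(method)
  curve <- response_curve(id, params, axis = "dose", grid = grid, at = tau,
                          method = method)
  y <- curve$response
  repeat {
    n <- length(y)
    imax <- which.max(y)
    E_max <- y[imax]
    bell <- imax < n && (E_max - y[n]) > 0.01 * E_max
    ## saturation check over the top decade of the grid
    dec <- which(grid >= grid[n] / 10)
    saturated <- bell ||
      (max(y[dec]) - min(y[dec])) <= 0.01 * E_max
    if (saturated) break
    if (!widen || grid[n] >= widen_cap) {
      stop("dose grid does not span saturation; widen the grid")
    }
    ext <- 10^seq(log10(grid[n]), log10(grid[n] * 10), length.out = 11)[-1]
    f <- if (method == "numeric") numeric_response else analytic_response
    y <- c(y, f(id, params, L_T = ext, tau = tau))
    grid <- c(grid, ext)
  }
  half <- E_max / 2
  rise <- which(y[seq_len(imax)] >= half)
  if (length(rise) == 0 || rise[1] == 1) {
    stop("EC_50 not bracketed on the rising branch; widen the grid downward")
  }
  i <- rise[1]
  f <- if (method == "numeric") numeric_response else analytic_response
  root <- stats::uniroot(
    function(lg) f(id, params, L_T = 10^lg, tau = tau) - half,
    lower = log10(grid[i - 1]), upper = log10(grid[i]),
    tol = 1e-4 / log(10)
  )
  tibble::tibble(model = id, tau = tau, E_max = E_max, EC_50 = 10^root$root,
                 branch = if (bell) "rising (bell-shaped curve)" else "rising",
                 method = method)
}

#' Analytic EC_50 where a main-text closed form exists
#'
#' Models 1, 2, 3 and 5 have `EC_50 = K_D + R_T/2`; model 6 has the same
#' form with the chain-effective dissociation constant. Other models
#' return `NA` (their closed forms involve composites defined only
#' through the models' steady-state structure).
#'
#' @inheritParams analytic_response
#' @return Scalar EC_50 (molecules/cell) or `NA`.
#' @export
analytic_ec50 <- function(id, params, tau = params$tau) {
  params <- refresh_tau(params, tau)
  K_D <- params$v / params$kappa
  if (id %in% c(1, 2, 3, 5)) K_D + params$R_T / 2
  else if (id == 6) stab_chain_aux(params)$K_D_eff + params$R_T / 2
  else NA_real_
}

#' Survival-probability ratio beyond a proofreading threshold
#'
#' For exponentially distributed bond lifetimes, the probability of
#' remaining bound beyond a threshold time is `exp(-threshold / tau)`; the
#' ratio for two ligands quantifies kinetic-proofreading specificity
#' (about 55 for 5 s vs 1 s ligands at a 5 s threshold).
#'
#' @param threshold Proofreading threshold time, s.
#' @param tau_long,tau_short Mean dissociation times of the two ligands, s.
#' @return The ratio `exp(threshold/tau_short - threshold/tau_long)`.
#' @export
specificity_ratio <- function(threshold = 5, tau_long = 5, tau_short = 1) {
  stopifnot(threshold > 0, tau_long > 0, tau_short > 0)
  exp(threshold / tau_short - threshold / tau_long)
}
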