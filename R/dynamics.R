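## ODE integration, steady-state location and stability classification.
##
## Steady states are found on the reduced system (conserved quantities
## eliminated), which removes the neutral directions along the
## stoichiometric compatibility class; eigenvalues of the reduced Jacobian
## are therefore the class-restricted ones.

## Internal: run code with a temporary RNG seed, restoring the caller's
## RNG state afterwards.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Integrate a model's mass-action ODEs
#'
#' Stiff-capable integration (lsoda) of the full system with the analytic
#' Jacobian generated from the reaction network.
#'
#' @param model A `tcell_model`.
#' @param init Initial full state (named or model-ordered); defaults to the
#'   resting, fully unbound state.
#' @param t_end End time, seconds.
#' @param n_out Number of output time points (log-ish dense early grid is
#'   not needed; the grid is uniform).
#' @param times Optional explicit output times overriding `t_end`/`n_out`.
#' @param rtol,atol Integration tolerances.
#' @return An object of class `tcell_trajectory`: list with `times`,
#'   `states` (time-by-species matrix), `model`, and `diagnostics`
#'   (solver, tolerances, final right-hand-side norm).
#' @export
simulate_model <- function(model, init = model$init, t_end = 1e4,
                           n_out = 200, times = NULL,
                           rtol = 1e-8, atol = 1e-10) {
  init <- as_model_state(model, init)
  if (any(init < 0)) stop("initial state must be nonnegative")
  if (is.null(times)) times <- seq(0, t_end, length.out = n_out)
  func <- function(t, y, parms) list(network_rhs(model$compiled, y))
  jacf <- function(t, y, parms) network_jacobian(model$compiled, y)
  out <- deSolve::ode(y = stats::setNames(init, model$species), times = times,
                      func = func, parms = NULL, jacfunc = jacf,
                      jactype = "fullusr", method = "lsoda",
                      rtol = rtol, atol = atol)
  diag_attr <- attributes(out)$istate
  states <- unname(as.matrix(out[, -1, drop = FALSE]))
  colnames(states) <- model$species
  fin <- states[nrow(states), ]
  structure(list(
    times = as.numeric(out[, 1]),
    states = states,
    model = model,
    diagnostics = list(solver = "lsoda", rtol = rtol, atol = atol,
                       istate = diag_attr,
                       final_rhs_norm = sqrt(sum(network_rhs(model$compiled, fin)^2)))
  ), class = "tcell_trajectory")
}

#' @export
print.tcell_trajectory <- function(x, ...) {
  cat("<tcell_trajectory> model ", x$model$id, ", ",
      length(x$times), " time points, t in [",
      min(x$times), ", ", max(x$times), "] s\n", sep = "")
  invisible(x)
}

## Internal: damped Newton iteration on the reduced system. The state is
## scaled by the bounding box of the invariant set so that species pools
## of very different magnitudes (e.g. phosphatase vs chain occupancies)
## do not wreck the conditioning of the Newton solve.
newton_root <- function(red, x0, max_iter = 100, tol = NULL) {
  scale <- max(vapply(red$model$conserved, `[[`, numeric(1), "total"), 1)
  if (is.null(tol)) tol <- 1e-11 * scale
  D <- pmax(pmin(red$upper, scale), 1e-8 * scale)
  x <- x0
  f <- red$rhs(x)
  stalled <- 0L
  for (it in seq_len(max_iter)) {
    nf <- sqrt(sum(f^2))
    if (nf < tol) break
    J <- red$jacobian(x)
    ## solve in units of the box: J D dy = -f, dx = D dy
    step <- tryCatch(D * solve(J * rep(D, each = nrow(J)), -f),
                     error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lam <- 1
    repeat {
      xn <- x + lam * step
      fn <- red$rhs(xn)
      if (sqrt(sum(fn^2)) < nf || lam < 1e-6) break
      lam <- lam / 2
    }
    stalled <- if (sqrt(sum(fn^2)) >= nf * (1 - 1e-12)) stalled + 1L else 0L
    if (stalled >= 5L) return(NULL)
    x <- xn
    f <- fn
  }
  if (sqrt(sum(f^2)) >= tol) return(NULL)
  ## one undamped polishing step: quadratic convergence takes the residual
  ## to machine precision, keeping tiny readouts relatively accurate
  J <- red$jacobian(x)
  step <- tryCatch(D * solve(J * rep(D, each = nrow(J)), -f),
                   error = function(e) NULL)
  if (!is.null(step)) {
    xn <- x + step
    if (sqrt(sum(red$rhs(xn)^2)) <= sqrt(sum(f^2))) x <- xn
  }
  x
}

## Internal: sample a feasible reduced start uniformly in K's bounding box,
## shrunk toward the origin until the full state is nonnegative.
sample_start <- function(red) {
  x <- stats::runif(length(red$upper)) * pmin(red$upper, .Machine$double.xmax)
  full <- red$to_full(x)
  if (any(full < 0)) {
    ## full state is affine in x and nonnegative at x = 0; scale back
    tmax <- 1
    for (i in which(full < 0)) {
      at0 <- red$to_full(numeric(length(x)))[i]
      slope <- full[i] - at0
      if (slope < 0) tmax <- min(tmax, 0.95 * at0 / (-slope))
    }
    x <- x * tmax
  }
  x
}

#' Locate all steady states in a stoichiometric compatibility class
#'
#' Multistart damped-Newton root finding on the reduced system, starts
#' sampled uniformly (seeded) in the compact invariant set K. Converged
#' roots are deduplicated at relative distance 1e-6, checked for
#' interiority (all species strictly positive) and classified for linear
#' stability via the reduced Jacobian.
#'
#' @param model A `tcell_model`.
#' @param n_starts Number of random starts (>= 1); the resting state and
#'   the box centre are always included as additional starts.
#' @param seed RNG seed for the start sample.
#' @param dedup_tol Relative deduplication distance.
#' @return A tibble with one row per steady state: list-column `state`
#'   (full named state), `readout`, `residual`, `interior`, `stability`
#'   (stable / unstable / marginal), `max_re_eigen`, and list-column
#'   `eigenvalues`.
#' @export
find_steady_states <- function(model, n_starts = 200, seed = 1,
                               dedup_tol = 1e-6) {
  stopifnot(n_starts >= 1)
  red <- reduce_by_conservation(model)
  scale <- max(vapply(model$conserved, `[[`, numeric(1), "total"))
  ## deterministic starts: the resting state, the box centre, and the
  ## terminal state of a forward integration from rest (which sits in the
  ## attractor reached from the biological resting state)
  attract <- tryCatch({
    tr <- simulate_model(model, t_end = 1e4, n_out = 3)
    fin <- pmax(tr$states[nrow(tr$states), ], 0)
    fin[match(red$kept, model$species)]
  }, error = function(e) NULL)
  starts <- with_seed(seed, {
    c(list(numeric(length(red$upper)),
           sample_start_center(red)),
      if (!is.null(attract)) list(attract),
      replicate(n_starts, sample_start(red), simplify = FALSE))
  })
  roots <- list()
  for (x0 in starts) {
    x <- newton_root(red, x0)
    if (is.null(x)) next
    full <- red$to_full(x)
    if (any(full < -1e-8 * scale)) next
    new <- TRUE
    for (r in roots) {
      if (sqrt(sum((r - x)^2)) <= dedup_tol * max(1, sqrt(sum(r^2)))) {
        new <- FALSE
        break
      }
    }
    if (new) roots[[length(roots) + 1]] <- x
  }
  if (length(roots) == 0) {
    warning("no steady state converged after ", n_starts, " starts")
  }
  rows <- lapply(roots, function(x) {
    full <- red$to_full(x)
    st <- classify_stability(model, full, red = red)
    tibble::tibble(
      state = list(full),
      readout = model_readout(model, full),
      residual = sqrt(sum(red$rhs(x)^2)),
      interior = all(full > 0),
      stability = st$stability,
      max_re_eigen = max(Re(st$eigenvalues)),
      eigenvalues = list(st$eigenvalues)
    )
  })
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(state = list(), readout = numeric(), residual = numeric(),
                   interior = logical(), stability = character(),
                   max_re_eigen = numeric(), eigenvalues = list())
  out <- out[order(-out$readout), ]
  attr(out, "model_id") <- model$id
  out
}

## Internal: centre of the feasible box as a deterministic extra start.
sample_start_center <- function(red) {
  x <- red$upper / (2 * length(red$upper))
  full <- red$to_full(x)
  if (any(full < 0)) x <- x * 0.5
  x
}

#' Classify linear stability of a steady state
#'
#' Eigenvalues of the Jacobian of the reduced system (class-restricted).
#' Stable if all real parts are below `-threshold`, marginal if any real
#' part lies within `threshold` of zero (including a singular Jacobian),
#' unstable otherwise.
#'
#' @param model A `tcell_model`.
#' @param state Full named steady state.
#' @param threshold Marginality threshold on eigenvalue real parts.
#' @param red Optional precomputed [reduce_by_conservation()] result.
#' @return List with `stability` (character) and `eigenvalues`.
#' @export
classify_stability <- function(model, state, threshold = 1e-9, red = NULL) {
  if (is.null(red)) red <- reduce_by_conservation(model)
  state <- as_model_state(model, state)
  xr <- state[match(red$kept, model$species)]
  J <- red$jacobian(xr)
  ev <- tryCatch(eigen(J, only.values = TRUE)$values,
                 error = function(e) NA)
  if (anyNA(ev)) {
    return(list(stability = "marginal", eigenvalues = ev))
  }
  re <- Re(ev)
  stability <- if (any(abs(re) <= threshold)) "marginal"
  else if (all(re < -threshold)) "stable"
  else "unstable"
  list(stability = stability, eigenvalues = ev)
}

#' Scan a (phi, tau, L_T) grid for multistability
#'
#' Runs [find_steady_states()] at every grid point and reports the
#' steady-state count and stability census. Intended for model 5 (KPR with
#' negative feedback); the other models are expected monostable.
#'
#' @param id Model id (default 5).
#' @param summary Parameter summary table; non-scanned parameters are
#'   taken from its `selector` column.
#' @param phi_grid,tau_grid,L_T_grid Grid values for the phosphorylation
#'   rate (1/s), dissociation time (s) and ligand dose (molecules/cell).
#' @param selector Column used for the non-scanned parameters.
#' @param N Proofreading depth.
#' @param n_starts Multistart count per grid point.
#' @param seed RNG seed.
#' @return A tibble with columns `phi`, `tau`, `L_T`, `n_states`,
#'   `n_interior`, `n_stable`, `n_unstable`, `n_marginal`.
#' @export
scan_multistability <- function(id = 5, summary = aggregate_sources(),
                                phi_grid = seq(0.535, 1, length.out = 5),
                                tau_grid = exp(seq(log(0.5), log(20),
                                                   length.out = 6)),
                                L_T_grid = 10^seq(2, 5, length.out = 7),
                                selector = "mean", N = 5,
                                n_starts = 60, seed = 1) {
  grid <- tidyr::expand_grid(phi = phi_grid, tau = tau_grid, L_T = L_T_grid)
  res <- purrr::pmap(grid, function(phi, tau, L_T) {
    params <- parameter_set(summary, selector = selector, L_T = L_T,
                            tau = tau, N = N, overrides = list(phi = phi))
    ss <- find_steady_states(build_model(id, params),
                             n_starts = n_starts, seed = seed)
    tibble::tibble(
      n_states = nrow(ss),
      n_interior = sum(ss$interior),
      n_stable = sum(ss$stability == "stable"),
      n_unstable = sum(ss$stability == "unstable"),
      n_marginal = sum(ss$stability == "marginal")
    )
  })
  dplyr::bind_cols(grid, dplyr::bind_rows(res))
}
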