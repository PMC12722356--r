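## Shared fixtures and independent oracles for the test suite.

mean_summary <- aggregate_sources()

mean_params <- function(L_T = 1e3, tau = 2, N = 5, ...) {
  parameter_set(mean_summary, "mean", L_T = L_T, tau = tau, N = N, ...)
}

## Independent PRCC oracle: explicit rank transformation and residual
## regressions via lm, no shared code with the package's precision-matrix
## implementation.
prcc_oracle <- function(samples, outputs) {
  X <- apply(as.matrix(samples), 2, rank)
  y <- rank(outputs)
  vapply(seq_len(ncol(X)), function(i) {
    others <- X[, -i, drop = FALSE]
    rx <- stats::residuals(stats::lm(X[, i] ~ others))
    ry <- stats::residuals(stats::lm(y ~ others))
    stats::cor(rx, ry)
  }, numeric(1))
}

## Random small mass-action network over a handful of species (for
## deficiency fuzzing).
random_network <- function(n_species = 4, n_rxn = 5) {
  sp <- LETTERS[seq_len(n_species)]
  lapply(seq_len(n_rxn), function(i) {
    pick <- function() {
      k <- sample(1:2, 1)
      tab <- table(sample(sp, k, replace = TRUE))
      stats::setNames(as.integer(tab), names(tab))
    }
    re <- pick()
    pr <- pick()
    while (identical(re, pr)) pr <- pick()
    reaction(re, pr, stats::runif(1), paste0("k", i))
  })
}

## Terminal state of a long integration.
terminal_state <- function(model, init = model$init, t_end = 1e6) {
  tr <- simulate_model(model, init = init, t_end = t_end, n_out = 3)
  tr$states[nrow(tr$states), ]
}

## Full-system rhs at an unnamed state vector (for finite-difference
## Jacobian checks).
network_rhs_for_test <- function(model, x) {
  unname(model_rhs(model, stats::setNames(x, model$species)))
}

## Seeded random feasible full-state starts for convergence checks.
with_seed_starts <- function(red, n, seed) {
  tcellkpr:::with_seed(seed, {
    lapply(seq_len(n), function(i) red$to_full(tcellkpr:::sample_start(red)))
  })
}
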