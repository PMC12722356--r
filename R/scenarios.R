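## Scenario generation: deterministic, seeded descriptions of every input
## the analysis pipeline consumes, so that all stages can be re-run
## without any external data.

#' The full study scenario set
#'
#' Enumerates the scenarios behind the comparative study: each of the
#' nine models at the mean / min / max parameter sets swept over ligand
#' dose and over dissociation time (54 scenarios), the model-5
#' multistability scan, and one LHS-PRCC study per model (64 in total).
#' Dose sweeps fix `tau` at 2 s; dissociation-time sweeps fix `L_T` at
#' 1e3 molecules/cell.
#'
#' Expected-feature annotations encode the qualitative behaviour of the
#' mean-parameter scenarios (interior optimum, bell shape, bimodality);
#' they drive the data-driven qualitative tests.
#'
#' @param N Proofreading depth used in every scenario.
#' @param seed Base seed; per-scenario seeds are derived deterministically.
#' @return A tibble with columns `name`, `kind`, `model`, `selector`,
#'   `L_T`, `tau`, `N`, `grid_min`, `grid_max`, `grid_n`, `seed`,
#'   `expected_features`.
#' @export
paper_scenarios <- function(N = 5, seed = 1) {
  sweeps <- tidyr::expand_grid(
    model = 1:9,
    selector = c("mean", "min", "max"),
    kind = c("dose_sweep", "tau_sweep")
  )
  sweeps <- dplyr::mutate(
    sweeps,
    name = sprintf("m%d_%s_%s", .data$model, .data$selector, .data$kind),
    L_T = 1e3, tau = 2, N = N,
    grid_min = ifelse(.data$kind == "dose_sweep", 1e-1, 1e-1),
    grid_max = ifelse(.data$kind == "dose_sweep", 1e7, 1e2),
    grid_n = ifelse(.data$kind == "dose_sweep", 200, 120)
  )
  ann <- c(
    "1" = "monotone",
    "2" = "monotone; emax_tau_dependent",
    "3" = "tau_optimum",
    "4" = "tau_optimum_low_dose_only; emax_tau_independent",
    "5" = "bell_dose_response",
    "6" = "monotone",
    "7" = "dose_curve_crossings; dose_optimum_high_tau",
    "8" = "bimodal_tau_response",
    "9" = "tau_optimum_retained_high_dose"
  )
  sweeps$expected_features <- ifelse(sweeps$selector == "mean",
                                     ann[as.character(sweeps$model)],
                                     NA_character_)
  scan <- tibble::tibble(
    name = "m5_multistability_scan", kind = "multistability_scan",
    model = 5, selector = "mean", L_T = NA_real_, tau = NA_real_, N = N,
    grid_min = NA_real_, grid_max = NA_real_, grid_n = NA_real_,
    expected_features = "three_steady_states_two_stable"
  )
  prcc <- tibble::tibble(
    name = sprintf("m%d_prcc", 1:9), kind = "prcc", model = 1:9,
    selector = "mean", L_T = 1e3, tau = 2, N = N,
    grid_min = NA_real_, grid_max = NA_real_, grid_n = 2000,
    expected_features = NA_character_
  )
  out <- dplyr::bind_rows(sweeps, scan, prcc)
  out$seed <- as.integer(seed) + seq_len(nrow(out)) - 1L
  out[, c("name", "kind", "model", "selector", "L_T", "tau", "N",
          "grid_min", "grid_max", "grid_n", "seed", "expected_features")]
}

#' Random parameter-set scenarios inside the literature ranges
#'
#' Seeded, reproducible draws of the eight shared parameters uniformly
#' inside their min-max ranges (log-uniform where the range spans two or
#' more orders of magnitude), with doses and dissociation times drawn
#' over the study's sweep windows. Used by property-style tests
#' (conservation, positivity, analytic/numeric agreement).
#'
#' @param n Number of scenarios (>= 1).
#' @param seed RNG seed; the result is a pure function of (`n`, `seed`).
#' @param summary Parameter summary providing the ranges.
#' @param N Proofreading depth.
#' @return A tibble with one row per scenario: the eight shared
#'   parameters, `L_T`, `tau`, `N`, `id` (suggested model), `seed`.
#' @export
fuzz_scenarios <- function(n, seed = 1, summary = aggregate_sources(),
                           N = 5) {
  stopifnot(n >= 1)
  shared <- c("R_T", "kappa", "S_T", "phi", "b", "gamma", "alpha", "beta")
  i <- match(shared, summary$parameter)
  lo <- summary$min[i]
  hi <- summary$max[i]
  use_log <- hi / lo >= 100
  draws <- with_seed(seed, {
    m <- matrix(stats::runif(n * length(shared)), n, length(shared))
    extra <- cbind(L_T = 10^stats::runif(n, 0, 5),
                   tau = 10^stats::runif(n, log10(0.5), log10(20)),
                   id = sample(1:9, n, replace = TRUE))
    list(m = m, extra = extra)
  })
  vals <- sapply(seq_along(shared), function(j) {
    if (use_log[j]) 10^(log10(lo[j]) + draws$m[, j] * (log10(hi[j]) - log10(lo[j])))
    else lo[j] + draws$m[, j] * (hi[j] - lo[j])
  })
  colnames(vals) <- shared
  out <- tibble::as_tibble(as.data.frame(cbind(vals, draws$extra)))
  out$N <- N
  out$seed <- seed
  out
}

#' Build a parameter set from one fuzz-scenario row
#'
#' @param row A one-row data frame from [fuzz_scenarios()].
#' @return A [parameter_set()].
#' @export
scenario_params <- function(row) {
  stub <- tibble::tibble(
    parameter = c("R_T", "kappa", "S_T", "phi", "b", "gamma", "alpha", "beta"),
    mean = unlist(row[c("R_T", "kappa", "S_T", "phi", "b", "gamma",
                        "alpha", "beta")])
  )
  stub$max <- stub$mean
  stub$min <- stub$mean
  parameter_set(stub, "mean", L_T = row$L_T, tau = row$tau, N = row$N)
}

#' Write / read the scenario table
#'
#' Scenarios serialize to YAML; a write-read round trip reproduces the
#' table exactly.
#'
#' @param scenarios A scenario tibble.
#' @param path File path.
#' @return `path` (write) or the scenario tibble (read).
#' @export
write_scenarios <- function(scenarios, path) {
  yaml::write_yaml(lapply(seq_len(nrow(scenarios)), function(i) {
    as.list(scenarios[i, ])
  }), path)
  invisible(path)
}

#' @rdname write_scenarios
#' @export
read_scenarios <- function(path) {
  rows <- yaml::read_yaml(path)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::as_tibble(lapply(r, function(v) if (is.null(v)) NA else v))
  }))
}
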