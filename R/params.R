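#' Literature source values for the shared TCR signalling parameters
#'
#' The comparative study draws its kinetic parameters from four experimental
#' modelling papers. Each source reports a subset of eight parameters; the
#' table keeps one row per (source, parameter) pair that the source actually
#' reports.
#'
#' Units: species totals (`R_T`, `S_T`) are molecules per cell; bimolecular
#' rates (`kappa`, `gamma`, `alpha`) are per molecule per second; first-order
#' rates (`phi`, `b`, `beta`) are per second.
#'
#' @return A tibble with columns `source` (character label), `parameter`
#'   (one of `R_T`, `kappa`, `S_T`, `phi`, `b`, `gamma`, `alpha`, `beta`),
#'   and `value`.
#' @export
#' @examples
#' source_table()
source_table <- function() {
  tibble::tribble(
    ~source,    ~parameter, ~value,
    "source_1", "R_T",      3e4,
    "source_2", "R_T",      1.5708e4,
    "source_3", "R_T",      2e4,
    "source_4", "R_T",      3e4,
    "source_1", "kappa",    1e-4,
    "source_2", "kappa",    3.1831e-5,
    "source_3", "kappa",    1e-4,
    "source_4", "kappa",    1e-5,
    "source_1", "S_T",      6e5,
    "source_2", "S_T",      6e5,
    "source_3", "S_T",      6e5,
    "source_4", "S_T",      3e5,
    "source_1", "phi",      0.09,
    "source_2", "phi",      1,
    "source_3", "phi",      1,
    "source_4", "phi",      0.05,
    "source_1", "b",        0.04,
    "source_2", "b",        0.04,
    "source_3", "b",        0.04,
    "source_4", "b",        0.02,
    "source_1", "gamma",    1.2e-6,
    "source_3", "gamma",    4.4e-4,
    "source_4", "gamma",    4.4e-4,
    "source_1", "alpha",    2e-4,
    "source_4", "alpha",    1e-4,
    "source_1", "beta",     1,
    "source_4", "beta",     6e-3
  )
}

#' Aggregate per-source parameter values into mean / max / min summaries
#'
#' The mean is the arithmetic mean over the sources that report the
#' parameter (three sources report `gamma`, two report `alpha` and `beta`);
#' max and min are the extrema over the same sources. Missing entries are
#' simply absent rows, never zeros.
#'
#' @param table A data frame with columns `source`, `parameter`, `value`,
#'   as returned by [source_table()].
#' @return A tibble with columns `parameter`, `mean`, `max`, `min`,
#'   `n_sources`.
#' @export
#' @examples
#' aggregate_sources(source_table())
aggregate_sources <- function(table = source_table()) {
  stopifnot(all(c("source", "parameter", "value") %in% names(table)))
  if (any(is.na(table$value))) {
    bad <- unique(table$parameter[is.na(table$value)])
    stop("missing value for parameter(s): ", paste(bad, collapse = ", "))
  }
  if (any(table$value <= 0)) {
    bad <- unique(table$parameter[table$value <= 0])
    stop("non-positive source value for parameter(s): ",
         paste(bad, collapse = ", "))
  }
  out <- table |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      mean = mean(.data$value),
      max = max(.data$value),
      min = min(.data$value),
      n_sources = dplyr::n(),
      .groups = "drop"
    )
  # keep the canonical ordering of the table
  out[match(unique(table$parameter), out$parameter), ]
}

#' Model-specific rate constants
#'
#' Constants that belong to individual model variants rather than to the
#' shared parameter table. All rates are per second unless noted.
#'
#' @param xi Limited-signalling exit rate: conversion of the
#'   signalling-competent bound state to a non-signalling bound state
#'   (models 3, 8, 9).
#' @param Omega Sustained-signalling reset rate: return of the unbound,
#'   still-signalling receptor to baseline (models 4, 9).
#' @param r_off Stabilizing-chain off-rate factor: the unbinding rate of
#'   chain state i is `v * r_off^(-i)` (model 6).
#' @param r_phos Stabilizing-chain phosphorylation factor: the forward rate
#'   out of state i is `phi * r_phos^i` (model 6).
#' @param iff_d,iff_c,iff_b,iff_a Incoherent feed-forward output-layer
#'   rates (models 7, 8): basal deactivation of X (`iff_d`), basal
#'   activation of X (`iff_c`), the remaining two source constants
#'   (`iff_b`, `iff_a`); `iff_a` is the deactivation rate of the
#'   intermediate Y, while `iff_b` does not enter the steady-state response
#'   and is retained for completeness.
#' @param m_total,l_total Pool sizes (molecules per cell) of the
#'   intermediate Y and the output X.
#' @param delta_act Y-mediated activation of X, per molecule of Y per
#'   second.
#' @param mu_inh Signalling-state-mediated deactivation of X, per molecule
#'   of C_N per second.
#' @param sigma_act Activation of Y by the signalling state C_N, per
#'   molecule of C_N per second.
#' @param eta Limited-signalling exit rate entering the model-8 analytic
#'   E_max expression; by construction equal to the chain's `xi` unless
#'   overridden.
#' @return A named list of class `tcell_constants`.
#' @export
model_constants <- function(xi = 0.09, Omega = 0.001,
                            r_off = 1.5, r_phos = 1.03,
                            iff_d = 500, iff_c = 1, iff_b = 500, iff_a = 1,
                            m_total = 100, l_total = 100,
                            delta_act = 50, mu_inh = 2.5, sigma_act = 0.5,
                            eta = xi) {
  out <- list(
    xi = xi, Omega = Omega, r_off = r_off, r_phos = r_phos,
    iff_d = iff_d, iff_c = iff_c, iff_b = iff_b, iff_a = iff_a,
    m_total = m_total, l_total = l_total,
    delta_act = delta_act, mu_inh = mu_inh, sigma_act = sigma_act,
    eta = eta
  )
  bad <- names(out)[!vapply(out, function(x) is.numeric(x) && length(x) == 1 && x > 0, TRUE)]
  if (length(bad) > 0) {
    stop("model constants must be positive scalars: ", paste(bad, collapse = ", "))
  }
  structure(out, class = "tcell_constants")
}

#' Build a fully resolved parameter set for one scenario
#'
#' Resolves the eight shared parameters to single values (one of the
#' mean / max / min columns of a summary table), attaches the scenario
#' variables (ligand dose `L_T`, dissociation time `tau`, proofreading
#' depth `N`) and the model constants, and applies any explicit overrides
#' last. The unbinding rate is always derived as `v = 1/tau`.
#'
#' @param summary A data frame as returned by [aggregate_sources()].
#' @param selector One of `"mean"`, `"max"`, `"min"`.
#' @param L_T Total ligand, molecules per cell (> 0).
#' @param tau Mean dissociation time of the TCR-pMHC bond, seconds (> 0).
#' @param N Number of proofreading steps (integer >= 1). The bound states
#'   are C_0 ... C_N.
#' @param constants A [model_constants()] list.
#' @param overrides Named list of fields to replace after selection, e.g.
#'   `list(phi = 0.8)`. Overrides of `tau` also refresh `v`.
#' @return An object of class `tcell_params`: a named list with fields
#'   `R_T`, `kappa`, `S_T`, `phi`, `b`, `gamma`, `alpha`, `beta`, `L_T`,
#'   `tau`, `v`, `N`, `constants`, `selector`, `overrides`.
#' @export
#' @examples
#' p <- parameter_set(selector = "mean", L_T = 1e3, tau = 2)
#' p$phi   # 0.535
#' p$v     # 0.5
parameter_set <- function(summary = aggregate_sources(),
                          selector = c("mean", "max", "min"),
                          L_T = 1e3, tau = 2, N = 5,
                          constants = model_constants(),
                          overrides = list()) {
  selector <- match.arg(selector)
  stopifnot(is.numeric(L_T), length(L_T) == 1, is.numeric(tau), length(tau) == 1)
  if (L_T <= 0) stop("L_T must be positive")
  if (tau <= 0) stop("tau must be positive")
  if (N < 1 || N != round(N)) stop("N must be an integer >= 1")
  need <- c("R_T", "kappa", "S_T", "phi", "b", "gamma", "alpha", "beta")
  if (!all(need %in% summary$parameter)) {
    stop("summary is missing parameter(s): ",
         paste(setdiff(need, summary$parameter), collapse = ", "))
  }
  vals <- summary[[selector]][match(need, summary$parameter)]
  names(vals) <- need
  p <- c(as.list(vals), list(L_T = L_T, tau = tau, v = 1 / tau, N = as.integer(N)))
  bad_over <- setdiff(names(overrides), c(names(p), names(unclass(constants))))
  if (length(bad_over) > 0) {
    stop("unknown override field(s): ", paste(bad_over, collapse = ", "))
  }
  for (nm in names(overrides)) {
    if (nm %in% names(unclass(constants))) {
      constants[[nm]] <- overrides[[nm]]
    } else {
      p[[nm]] <- overrides[[nm]]
    }
  }
  if ("tau" %in% names(overrides) && !("v" %in% names(overrides))) {
    p$v <- 1 / p$tau
  }
  rates <- unlist(p[c("R_T", "kappa", "S_T", "phi", "b", "gamma", "alpha",
                      "beta", "L_T", "tau", "v")])
  if (any(rates < 0)) stop("all rates and totals must be nonnegative")
  stopifnot(abs(p$v * p$tau - 1) <= 1e-12 * max(1, p$v * p$tau))
  structure(
    c(p, list(constants = constants, selector = selector,
              overrides = overrides)),
    class = "tcell_params"
  )
}

#' @export
print.tcell_params <- function(x, ...) {
  cat("<tcell_params> selector =", x$selector,
      if (length(x$overrides)) paste0("(", length(x$overrides), " override(s))"),
      "\n")
  flds <- c("R_T", "kappa", "S_T", "phi", "b", "gamma", "alpha", "beta",
            "L_T", "tau", "v", "N")
  cat(paste0("  ", flds, " = ", signif(unlist(x[flds]), 6), collapse = "\n"), "\n")
  invisible(x)
}

#' Serialize a parameter set to a flat YAML file
#'
#' The on-disk form is a flat key-value mapping: shared parameters and
#' scenario variables at the top level, model constants prefixed with
#' `const_`.
#'
#' @param params A `tcell_params` object.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_parameter_set <- function(params, path) {
  stopifnot(inherits(params, "tcell_params"))
  flat <- params[c("R_T", "kappa", "S_T", "phi", "b", "gamma", "alpha",
                   "beta", "L_T", "tau", "v", "N")]
  const <- unclass(params$constants)
  names(const) <- paste0("const_", names(const))
  flat <- c(flat, const, list(selector = params$selector))
  yaml::write_yaml(flat, path, precision = 15)
  invisible(path)
}

#' Read a parameter set written by [write_parameter_set()]
#'
#' @param path File path to read.
#' @return A `tcell_params` object.
#' @export
read_parameter_set <- function(path) {
  flat <- yaml::read_yaml(path)
  cn <- grepl("^const_", names(flat))
  constants <- do.call(model_constants, stats::setNames(
    flat[cn], sub("^const_", "", names(flat)[cn])))
  shared <- flat[!cn]
  summary_stub <- tibble::tibble(
    parameter = c("R_T", "kappa", "S_T", "phi", "b", "gamma", "alpha", "beta"),
    mean = unname(unlist(shared[c("R_T", "kappa", "S_T", "phi", "b",
                                  "gamma", "alpha", "beta")]))
  )
  summary_stub$max <- summary_stub$mean
  summary_stub$min <- summary_stub$mean
  parameter_set(summary_stub, selector = shared$selector %||% "mean",
                L_T = shared$L_T, tau = shared$tau, N = shared$N,
                constants = constants)
}
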