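## Qualitative feature classification of response curves: interior optima,
## local-maximum (mode) counts, monotonicity, and crossings between
## dose-response curves.

#' Detect an interior optimum in a response curve
#'
#' The verdict is `"interior_optimum"` when the global maximum of the
#' curve is interior and exceeds both endpoint values by at least
#' `rel_threshold` relatively; `"flat"` when the curve's range is
#' numerically zero; `"none"` otherwise.
#'
#' @param curve A `tcell_curve` (or any data frame with columns `x` and
#'   `response`).
#' @param rel_threshold Relative prominence threshold (default 1%: below
#'   figure-reading precision, above floating noise).
#' @return A one-row tibble: `verdict`, `x_opt`, `value`, `rel_threshold`.
#' @export
detect_optimum <- function(curve, rel_threshold = 0.01) {
  y <- curve$response
  x <- curve$x
  if (length(y) < 5) stop("need at least 5 grid points")
  rng <- max(y) - min(y)
  if (rng < 1e-12 * max(abs(y), 1e-300)) {
    return(tibble::tibble(verdict = "flat", x_opt = NA_real_,
                          value = NA_real_, rel_threshold = rel_threshold))
  }
  i <- which.max(y)
  interior <- i > 1 && i < length(y)
  exceeds <- y[i] >= y[1] * (1 + rel_threshold) &&
    y[i] >= y[length(y)] * (1 + rel_threshold)
  tibble::tibble(
    verdict = if (interior && exceeds) "interior_optimum" else "none",
    x_opt = if (interior && exceeds) x[i] else NA_real_,
    value = y[i],
    rel_threshold = rel_threshold
  )
}

#' Count prominent interior local maxima of a curve
#'
#' Equal-value runs are collapsed first (plateaus count once); a local
#' maximum is counted when its topographic prominence exceeds
#' `rel_threshold` times the curve's range.
#'
#' @inheritParams detect_optimum
#' @return Integer count.
#' @export
count_local_maxima <- function(curve, rel_threshold = 0.01) {
  y <- curve$response
  if (length(y) < 5) stop("need at least 5 grid points")
  v <- rle(y)$values
  n <- length(v)
  if (n < 3) return(0L)
  rng <- max(v) - min(v)
  if (rng <= 0) return(0L)
  idx <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]) + 1L
  cnt <- 0L
  for (i in idx) {
    hiL <- which(v[1:(i - 1)] > v[i])
    mL <- if (length(hiL)) min(v[max(hiL):i]) else min(v[1:i])
    hiR <- which(v[(i + 1):n] > v[i])
    mR <- if (length(hiR)) min(v[i:(i + min(hiR))]) else min(v[i:n])
    if (v[i] - max(mL, mR) > rel_threshold * rng) cnt <- cnt + 1L
  }
  cnt
}

#' Locate crossings between two response curves on a common grid
#'
#' Sign changes of the difference are located by linear interpolation.
#' Identical curves (difference below 1e-12 of scale everywhere) return an
#' empty result flagged `identical`.
#'
#' @param c1,c2 Curves sharing the same `x` grid.
#' @return A tibble with column `x_cross`; attribute `identical` is `TRUE`
#'   when the curves coincide.
#' @export
curves_cross <- function(c1, c2) {
  if (length(c1$x) != length(c2$x) || any(c1$x != c2$x)) {
    stop("curves must share a common grid")
  }
  d <- c1$response - c2$response
  scale <- max(abs(c(c1$response, c2$response)), 1e-300)
  out_attr <- FALSE
  if (all(abs(d) <= 1e-12 * scale)) {
    out <- tibble::tibble(x_cross = numeric())
    out_attr <- TRUE
  } else {
    i <- which(d[-1] * d[-length(d)] < 0)
    x <- c1$x
    x_cross <- x[i] + (x[i + 1] - x[i]) * abs(d[i]) / (abs(d[i]) + abs(d[i + 1]))
    ## exact zeros interior to the grid count once
    z <- setdiff(which(d == 0), c(1, length(d)))
    out <- tibble::tibble(x_cross = sort(c(x_cross, x[z])))
  }
  attr(out, "identical") <- out_attr
  out
}

#' Qualitative feature matrix across the nine models
#'
#' For each model, computes the dose-response reference metrics
#' (`E_max`, `EC_50` at `tau_ref`), probes dose curves at several
#' dissociation times for interior optima, probes dissociation-time
#' curves at model-relative doses (a tenth of the model's own `EC_50`,
#' ten times it, and the interior dose-optimum location where one exists)
#' for optima and mode counts, counts crossings between two dose curves,
#' and tests whether `E_max` depends on dissociation time.
#'
#' Dissociation-time optima are assessed on the standard window
#' 0.1-100 s; mode counting uses a wider window (0.1-1e4 s, spanning the
#' timescale of the slowest reset rates) so that slow-timescale second
#' modes are not truncated.
#'
#' @param summary Parameter summary table ([aggregate_sources()]).
#' @param selector Parameter column to use.
#' @param ids Model ids.
#' @param N Proofreading depth.
#' @param tau_ref Reference dissociation time for `EC_50` (s).
#' @param tau_probe Dissociation times for the dose-curve probes (s).
#' @param rel_threshold Prominence threshold for all verdicts.
#' @param n_dose,n_tau Grid sizes.
#' @return A tibble, one row per model, with verdict columns (see
#'   Details) and the threshold recorded in `rel_threshold`. Per-model
#'   failures are caught and reported in the `error` column without
#'   aborting the matrix.
#' @export
feature_matrix <- function(summary = aggregate_sources(),
                           selector = "mean", ids = 1:9, N = 5,
                           tau_ref = 2, tau_probe = c(0.5, 2, 10),
                           rel_threshold = 0.01,
                           n_dose = 160, n_tau = 160) {
  purrr::map_dfr(ids, function(id) {
    res <- tryCatch(
      feature_row(id, summary, selector, N, tau_ref, tau_probe,
                  rel_threshold, n_dose, n_tau),
      error = function(e) {
        tibble::tibble(model = id, name = model_names[id],
                       error = conditionMessage(e))
      })
    res
  })
}

## Internal: one row of the feature matrix.
feature_row <- function(id, summary, selector, N, tau_ref, tau_probe,
                        rel_threshold, n_dose, n_tau) {
  params <- parameter_set(summary, selector = selector, L_T = 1e3,
                          tau = tau_ref, N = N)
  dgrid <- dose_grid(n_dose)
  tgrid_opt <- tau_grid(n_tau, 1e-1, 1e2)
  tgrid_mode <- tau_grid(n_tau + 60, 1e-1, 1e4)

  ## dose curves at the probe dissociation times
  dose_curves <- lapply(tau_probe, function(tv) {
    response_curve(id, params, axis = "dose", grid = dgrid, at = tv)
  })
  names(dose_curves) <- paste0("tau", tau_probe)
  opt_dose <- vapply(dose_curves, function(cv) {
    detect_optimum(cv, rel_threshold)$verdict == "interior_optimum"
  }, logical(1))

  ## reference dose metrics and model-relative probe doses
  ref <- emax_ec50(id, params, tau = tau_ref, grid = dose_grid(200))
  ref_curve <- dose_curves[[match(tau_ref, tau_probe)]] %||% dose_curves[[1]]
  opt_ref <- detect_optimum(ref_curve, rel_threshold)
  peak_dose <- opt_ref$x_opt
  probe_doses <- c(low = ref$EC_50 / 10, high = 10 * ref$EC_50,
                   peak = peak_dose)

  tau_curves <- lapply(probe_doses, function(L) {
    if (is.na(L)) return(NULL)
    response_curve(id, params, axis = "tau", grid = tgrid_opt, at = L)
  })
  opt_tau <- vapply(tau_curves, function(cv) {
    if (is.null(cv)) NA else
      detect_optimum(cv, rel_threshold)$verdict == "interior_optimum"
  }, logical(1))

  mode_curves <- lapply(probe_doses, function(L) {
    if (is.na(L)) return(NULL)
    response_curve(id, params, axis = "tau", grid = tgrid_mode, at = L)
  })
  n_modes <- max(vapply(mode_curves, function(cv) {
    if (is.null(cv)) 0L else count_local_maxima(cv, rel_threshold)
  }, integer(1)))

  ## crossings between two dose curves (tau = 1 s vs 10 s)
  cr <- curves_cross(
    response_curve(id, params, axis = "dose", grid = dgrid, at = 1),
    dose_curves[["tau10"]] %||%
      response_curve(id, params, axis = "dose", grid = dgrid, at = 10)
  )

  ## E_max dependence on dissociation time
  emaxes <- vapply(tau_probe, function(tv) {
    emax_ec50(id, params, tau = tv, grid = dose_grid(200))$E_max
  }, numeric(1))
  emax_dep <- (max(emaxes) - min(emaxes)) > rel_threshold * max(emaxes)

  tibble::tibble(
    model = id, name = model_names[id],
    E_max_ref = ref$E_max, EC_50_ref = ref$EC_50,
    opt_dose_any = any(opt_dose),
    opt_dose_tau_low = opt_dose[[1]],
    opt_dose_tau_ref = opt_dose[[min(2, length(opt_dose))]],
    opt_dose_tau_high = opt_dose[[length(opt_dose)]],
    opt_tau_low_dose = opt_tau[["low"]],
    opt_tau_high_dose = opt_tau[["high"]],
    opt_tau_peak_dose = opt_tau[["peak"]],
    n_tau_modes = n_modes,
    n_crossings = nrow(cr),
    emax_tau_dependent = emax_dep,
    rel_threshold = rel_threshold,
    error = NA_character_
  )
}
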