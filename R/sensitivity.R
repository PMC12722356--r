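## LHS-PRCC sensitivity analysis: stratified Latin-hypercube sampling over
## literature parameter ranges and partial rank correlation coefficients
## of the model response with respect to each sampled parameter.

#' Latin hypercube sample over parameter ranges
#'
#' One stratified sample per parameter: for each parameter exactly one
#' draw falls in each of the `n` equal-probability strata of its range
#' (on the sampling scale), with independent stratum permutations across
#' parameters.
#'
#' @param ranges A data frame with columns `parameter`, `min`, `max` and
#'   optionally `scale` (`"linear"` or `"log"`); or a named list of
#'   `c(min, max)` pairs. When `scale` is absent, parameters whose ranges
#'   span at least two orders of magnitude are sampled log-uniformly.
#' @param n Number of samples (>= 2).
#' @param seed RNG seed; the design is a pure function of
#'   (`ranges`, `n`, `seed`).
#' @return An object of class `lhs_design`: the sample tibble (n rows,
#'   one column per parameter, in natural units) with attributes `ranges`
#'   (including the resolved scales), `seed`, and `n`.
#' @export
lhs_sample <- function(ranges, n, seed = 1) {
  stopifnot(n >= 2)
  if (!is.data.frame(ranges)) {
    ranges <- tibble::tibble(
      parameter = names(ranges),
      min = vapply(ranges, `[`, numeric(1), 1),
      max = vapply(ranges, `[`, numeric(1), 2)
    )
  }
  stopifnot(all(c("parameter", "min", "max") %in% names(ranges)))
  bad <- ranges$parameter[!(ranges$min < ranges$max)]
  if (length(bad)) {
    stop("degenerate range for parameter(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(ranges[["scale"]])) {
    ranges$scale <- ifelse(ranges$min > 0 & ranges$max / ranges$min >= 100,
                           "log", "linear")
  }
  stopifnot(all(ranges$scale %in% c("linear", "log")),
            all(ranges$min > 0 | ranges$scale == "linear"))
  k <- nrow(ranges)
  u <- with_seed(seed, lhs::randomLHS(n, k))
  x <- matrix(NA_real_, n, k, dimnames = list(NULL, ranges$parameter))
  for (j in seq_len(k)) {
    if (ranges$scale[j] == "log") {
      x[, j] <- 10^(log10(ranges$min[j]) +
                      u[, j] * (log10(ranges$max[j]) - log10(ranges$min[j])))
    } else {
      x[, j] <- ranges$min[j] + u[, j] * (ranges$max[j] - ranges$min[j])
    }
  }
  out <- tibble::as_tibble(as.data.frame(x))
  class(out) <- c("lhs_design", class(out))
  attr(out, "ranges") <- ranges
  attr(out, "seed") <- seed
  attr(out, "n") <- n
  out
}

#' Partial rank correlation coefficients
#'
#' All columns are rank-transformed (average ranks on ties); the
#' coefficient for each parameter is the correlation between the
#' residuals of the parameter and of the output after linearly partialling
#' out all other parameters, computed via the precision matrix of the
#' rank correlations.
#'
#' @param samples A data frame of sampled parameter values (one column
#'   per parameter).
#' @param outputs Numeric model outputs, one per row of `samples`.
#' @param n_boot Number of bootstrap resamples for percentile confidence
#'   intervals (0 to skip).
#' @param conf Confidence level for the bootstrap interval.
#' @param seed Seed for the bootstrap resampling.
#' @return A tibble with columns `parameter`, `prcc`, `ci_low`, `ci_high`,
#'   `n`.
#' @export
prcc <- function(samples, outputs, n_boot = 0, conf = 0.95, seed = 1) {
  samples <- as.data.frame(samples)
  stopifnot(nrow(samples) == length(outputs))
  if (!all(is.finite(outputs))) stop("outputs must be finite")
  k <- ncol(samples)
  n <- nrow(samples)
  if (n <= k + 2) stop("need more samples than parameters + 2")
  if (stats::sd(outputs) == 0) {
    warning("constant output: all PRCCs set to zero")
    return(tibble::tibble(parameter = names(samples), prcc = 0,
                          ci_low = NA_real_, ci_high = NA_real_, n = n))
  }
  est <- prcc_estimate(samples, outputs)
  ci <- matrix(NA_real_, k, 2)
  if (n_boot > 0) {
    boots <- with_seed(seed, {
      replicate(n_boot, {
        idx <- sample.int(n, n, replace = TRUE)
        prcc_estimate(samples[idx, , drop = FALSE], outputs[idx])
      })
    })
    probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
    ci <- t(apply(boots, 1, stats::quantile, probs = probs, na.rm = TRUE))
  }
  tibble::tibble(parameter = names(samples), prcc = est,
                 ci_low = ci[, 1], ci_high = ci[, 2], n = n)
}

## Internal: PRCC point estimate via the precision matrix of the rank
## correlation matrix; degenerate (collinear) cases fall back to explicit
## QR residual projections.
prcc_estimate <- function(samples, outputs) {
  k <- ncol(samples)
  R <- apply(cbind(as.matrix(samples), outputs), 2, rank)
  C <- stats::cor(R)
  P <- tryCatch(solve(C), error = function(e) NULL)
  if (!is.null(P) && all(diag(P) > 0) && rcond(C) > 1e-10) {
    return(vapply(seq_len(k), function(i) {
      -P[i, k + 1] / sqrt(P[i, i] * P[k + 1, k + 1])
    }, numeric(1)))
  }
  ## fallback: residuals of each rank column and of the rank output
  ## after projecting out the remaining rank columns
  y <- R[, k + 1]
  vapply(seq_len(k), function(i) {
    others <- cbind(1, R[, -c(i, k + 1), drop = FALSE])
    rx <- stats::resid(stats::lm.fit(others, R[, i]))
    ry <- stats::resid(stats::lm.fit(others, y))
    if (stats::sd(rx) < 1e-12 * nrow(R) || stats::sd(ry) < 1e-12 * nrow(R)) {
      return(0)
    }
    stats::cor(rx, ry)
  }, numeric(1))
}

#' Default sampled-parameter ranges for a model's PRCC study
#'
#' Shared parameters use the literature min-max ranges (log-uniform for
#' the wide-ranged kappa, gamma and beta, linear otherwise); model-specific
#' constants, for which the sources print single values, are sampled
#' log-uniformly over a factor of 10 around their defaults; the
#' stabilizing-chain factors r_off and r_phos are sampled linearly above 1.
#'
#' @param id Model id, 1..9.
#' @param summary Parameter summary table.
#' @param include_v,include_L_T Also sample the unbinding rate `v`
#'   (0.05-2 per s, i.e. tau 0.5-20 s) and the ligand dose
#'   (1e2-1e5 molecules/cell).
#' @return A ranges tibble suitable for [lhs_sample()].
#' @export
prcc_ranges <- function(id, summary = aggregate_sources(),
                        include_v = FALSE, include_L_T = FALSE) {
  shared <- function(p) {
    i <- match(p, summary$parameter)
    tibble::tibble(parameter = p, min = summary$min[i], max = summary$max[i],
                   scale = ifelse(p %in% c("kappa", "gamma", "beta"),
                                  "log", "linear"))
  }
  const <- function(p, default) {
    tibble::tibble(parameter = p, min = default / 10, max = default * 10,
                   scale = "log")
  }
  base <- shared(c("R_T", "kappa"))
  extra <- switch(as.character(id),
    "1" = NULL,
    "2" = shared("phi"),
    "3" = dplyr::bind_rows(shared("phi"), const("xi", 0.09)),
    "4" = dplyr::bind_rows(shared("phi"), const("Omega", 0.001)),
    "5" = shared(c("phi", "b", "gamma", "alpha", "beta", "S_T")),
    "6" = dplyr::bind_rows(
      shared("phi"),
      tibble::tibble(parameter = c("r_off", "r_phos"),
                     min = c(1.05, 1.003), max = c(3, 1.3),
                     scale = "linear")),
    "7" = dplyr::bind_rows(shared("phi"),
                           const(c("sigma_act", "delta_act", "mu_inh"),
                                 c(0.5, 50, 2.5))),
    "8" = dplyr::bind_rows(shared("phi"),
                           const(c("sigma_act", "delta_act", "mu_inh"),
                                 c(0.5, 50, 2.5)),
                           const("xi", 0.09)),
    "9" = dplyr::bind_rows(shared("phi"), const("xi", 0.09),
                           const("Omega", 0.001))
  )
  out <- dplyr::bind_rows(base, extra)
  if (include_v) {
    out <- dplyr::bind_rows(out, tibble::tibble(parameter = "v",
                                                min = 0.05, max = 2,
                                                scale = "linear"))
  }
  if (include_L_T) {
    out <- dplyr::bind_rows(out, tibble::tibble(parameter = "L_T",
                                                min = 1e2, max = 1e5,
                                                scale = "log"))
  }
  out
}

#' Run an LHS-PRCC sensitivity study for one model
#'
#' Draws a Latin hypercube sample over the model's parameter ranges,
#' evaluates the numeric steady-state response at the study conditions
#' (by default `L_T` = 1e3 molecules/cell, `tau` = 2 s, with only the
#' model parameters sampled), and computes PRCCs. Rows where the
#' steady-state solve fails are dropped; more than `max_fail_frac`
#' failures aborts with diagnostics.
#'
#' @param id Model id, 1..9.
#' @param n Number of LHS rows.
#' @param seed RNG seed.
#' @param summary Parameter summary table; non-sampled parameters are
#'   fixed at its mean column.
#' @param L_T,tau Study conditions.
#' @param N Proofreading depth.
#' @param ranges Optional ranges tibble overriding [prcc_ranges()].
#' @param n_boot Bootstrap resamples for the PRCC confidence intervals.
#' @param max_fail_frac Maximum tolerated fraction of failed rows.
#' @return A tibble as from [prcc()] with additional columns `model` and
#'   attributes `n_failed`, `design`.
#' @export
run_prcc_study <- function(id, n = 2000, seed = 1,
                           summary = aggregate_sources(),
                           L_T = 1e3, tau = 2, N = 5, ranges = NULL,
                           n_boot = 0, max_fail_frac = 0.01) {
  ranges <- ranges %||% prcc_ranges(id, summary)
  design <- lhs_sample(ranges, n, seed = seed)
  const_names <- names(unclass(model_constants()))
  outputs <- vapply(seq_len(n), function(i) {
    row <- as.list(design[i, ])
    tau_i <- if ("v" %in% names(row)) 1 / row$v else tau
    L_i <- if ("L_T" %in% names(row)) row$L_T else L_T
    over <- row[setdiff(names(row), c("v", "L_T"))]
    tryCatch({
      params <- parameter_set(summary, "mean", L_T = L_i, tau = tau_i,
                              N = N, overrides = over)
      numeric_response(id, params)
    }, error = function(e) NA_real_)
  }, numeric(1))
  failed <- !is.finite(outputs)
  if (mean(failed) > max_fail_frac) {
    stop(sum(failed), " of ", n, " rows failed the steady-state solve ",
         "(limit ", round(100 * max_fail_frac, 1), "%)")
  }
  res <- prcc(design[!failed, , drop = FALSE], outputs[!failed],
              n_boot = n_boot, seed = seed)
  res <- dplyr::bind_cols(tibble::tibble(model = id), res)
  attr(res, "n_failed") <- sum(failed)
  attr(res, "design") <- design
  res
}
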