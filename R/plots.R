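## ggplot2 display methods for the package's result objects.

#' Plot a response curve
#'
#' @param object A `tcell_curve` from [response_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tcell_curve
#' @export
autoplot.tcell_curve <- function(object, ...) {
  xlab <- if (attr(object, "axis") == "dose") {
    "ligand dose L_T (molecules/cell)"
  } else {
    "dissociation time tau (s)"
  }
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$response)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = xlab, y = "response (readout, counts/cell)",
                  title = model_names[object$model[1]]) +
    ggplot2::theme_minimal()
}

#' Plot a trajectory
#'
#' @param object A `tcell_trajectory` from [simulate_model()].
#' @param species Optional subset of species to show.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tcell_trajectory
#' @export
autoplot.tcell_trajectory <- function(object, species = NULL, ...) {
  df <- tidy(object)
  if (!is.null(species)) df <- df[df$species %in% species, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "counts/cell",
                  title = object$model$name) +
    ggplot2::theme_minimal()
}

#' Tornado plot of PRCC results
#'
#' @param object A tibble from [prcc()] or [run_prcc_study()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_prcc <- function(object, ...) {
  df <- dplyr::arrange(object, .data$prcc)
  df$parameter <- factor(df$parameter, levels = df$parameter)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$prcc, y = .data$parameter)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "PRCC", y = NULL) +
    ggplot2::xlim(-1, 1) +
    ggplot2::theme_minimal()
  if (!all(is.na(df$ci_low))) {
    p <- p + ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2)
  }
  p
}
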