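## broom-style tidiers for the package's result objects.

#' Tidy a trajectory into long format
#'
#' @param x A `tcell_trajectory`.
#' @param ... Unused.
#' @return A tibble with columns `time`, `species`, `value`.
#' @method tidy tcell_trajectory
#' @export
tidy.tcell_trajectory <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$states)) |>
    dplyr::mutate(time = x$times, .before = 1) |>
    tidyr::pivot_longer(-"time", names_to = "species", values_to = "value")
}

#' One-row summary of a trajectory
#'
#' @param x A `tcell_trajectory`.
#' @param ... Unused.
#' @return A tibble with the model id, time span, final readout and final
#'   right-hand-side norm.
#' @method glance tcell_trajectory
#' @export
glance.tcell_trajectory <- function(x, ...) {
  fin <- x$states[nrow(x$states), ]
  tibble::tibble(
    model = x$model$id,
    t_end = max(x$times),
    final_readout = model_readout(x$model, fin),
    final_rhs_norm = x$diagnostics$final_rhs_norm
  )
}

#' One-row summary of a model
#'
#' @param x A `tcell_model`.
#' @param ... Unused.
#' @return A tibble with id, name, species / reaction / conserved counts
#'   and the readout label.
#' @method glance tcell_model
#' @export
glance.tcell_model <- function(x, ...) {
  tibble::tibble(
    model = x$id, name = x$name,
    n_species = length(x$species),
    n_reactions = length(x$reactions),
    n_conserved = length(x$conserved),
    readout = paste(names(x$readout), collapse = " + ")
  )
}

#' Tidy the complex graph of a CRN structure
#'
#' @param x A `crn_structure`.
#' @param ... Unused.
#' @return The edge tibble (columns `from`, `to`).
#' @method tidy crn_structure
#' @export
tidy.crn_structure <- function(x, ...) x$edges

#' One-row summary of a CRN structure
#'
#' @param x A `crn_structure`.
#' @param ... Unused.
#' @return A tibble with `n_complexes`, `linkage_classes`, `rank`,
#'   `deficiency`, `weakly_reversible`.
#' @method glance crn_structure
#' @export
glance.crn_structure <- function(x, ...) {
  tibble::tibble(
    n_complexes = x$n_complexes,
    linkage_classes = x$linkage_classes,
    rank = x$rank,
    deficiency = x$deficiency,
    weakly_reversible = x$weakly_reversible
  )
}
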