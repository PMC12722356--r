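## Chemical-reaction-network structural analysis: complexes, linkage
## classes, rank, deficiency (delta = n - l - s) and weak reversibility.
## The deficiency-zero theorem then guarantees, for weakly reversible
## networks, a unique asymptotically stable positive steady state in each
## stoichiometric compatibility class.

#' Structural analysis of a reaction network
#'
#' Computes the distinct complexes, the directed reaction graph on
#' complexes, the number of linkage classes (connected components of the
#' undirected complex graph), the network rank (rank of the span of the
#' reaction vectors, computed exactly on the integer stoichiometry), the
#' deficiency `delta = n_complexes - l - s`, and weak reversibility (every
#' reaction's complexes lie in a common strongly connected component).
#'
#' For models 4 and 9 the structural network differs from the simulated
#' one: the post-unbinding signalling receptor is bookkept as still
#' ligand-associated (its reset releases ligand and receptor together),
#' which is the representation in which the sustained-signalling networks
#' are weakly reversible with deficiency zero.
#'
#' @param model A `tcell_model`, or a list of `tcell_reaction`s together
#'   with `species`.
#' @param species Species vector (only needed when `model` is a raw
#'   reaction list).
#' @param structural Use the model's structural network where it defines
#'   one (default `TRUE`).
#' @return An object of class `crn_structure`: list with `complexes`
#'   (character labels), `n_complexes`, `linkage_classes` (`l`), `rank`
#'   (`s`), `deficiency`, `weakly_reversible`, and the complex `edges`
#'   tibble.
#' @export
#' @examples
#' cs <- crn_structure(build_model(3, parameter_set(N = 2)))
#' cs$deficiency          # 0
#' cs$weakly_reversible   # TRUE
crn_structure <- function(model, species = NULL, structural = TRUE) {
  if (inherits(model, "tcell_model")) {
    rxns <- if (structural) crn_reactions(model) else model$reactions
    species <- model$species
  } else {
    rxns <- model
    if (is.null(species)) {
      species <- unique(unlist(lapply(rxns, function(r) {
        c(names(r$reactants), names(r$products))
      })))
    }
  }
  complexes <- extract_complexes(rxns)
  n <- length(complexes)
  if (n == 0) {
    return(structure(list(complexes = character(), n_complexes = 0L,
                          linkage_classes = 0L, rank = 0L, deficiency = 0L,
                          weakly_reversible = TRUE,
                          edges = tibble::tibble(from = character(),
                                                 to = character())),
                     class = "crn_structure"))
  }
  lab <- function(v) complex_label(v)
  edges <- tibble::tibble(
    from = vapply(rxns, function(r) lab(r$reactants), character(1)),
    to = vapply(rxns, function(r) lab(r$products), character(1))
  )
  g <- igraph::graph_from_data_frame(unique(edges), directed = TRUE,
                                     vertices = complexes)
  l <- igraph::count_components(g, mode = "weak")
  scc <- igraph::components(g, mode = "strong")$membership
  wr <- all(scc[edges$from] == scc[edges$to])
  ## reaction vectors in species space, exact integer rank
  vecs <- vapply(rxns, function(r) {
    v <- stats::setNames(numeric(length(species)), species)
    v[names(r$reactants)] <- v[names(r$reactants)] - r$reactants
    v[names(r$products)] <- v[names(r$products)] + r$products
    v
  }, numeric(length(species)))
  s <- integer_rank(t(vecs))
  delta <- n - l - s
  if (delta < 0) {
    stop("internal error: negative deficiency (rank computation bug)")
  }
  structure(list(complexes = complexes, n_complexes = n,
                 linkage_classes = as.integer(l), rank = as.integer(s),
                 deficiency = as.integer(delta),
                 weakly_reversible = wr, edges = edges),
            class = "crn_structure")
}

#' @export
print.crn_structure <- function(x, ...) {
  cat("<crn_structure> n =", x$n_complexes, " l =", x$linkage_classes,
      " s =", x$rank, " deficiency =", x$deficiency,
      " weakly reversible:", x$weakly_reversible, "\n")
  invisible(x)
}

## Internal: canonical label of a complex (multiset of species).
complex_label <- function(v) {
  v <- v[v > 0]
  v <- v[order(names(v))]
  paste(ifelse(v > 1, paste0(v, " "), ""), names(v), sep = "", collapse = " + ")
}

#' Distinct complexes of a reaction list
#'
#' @param rxns A list of `tcell_reaction`s (or a `tcell_model`).
#' @return Character vector of canonical complex labels.
#' @export
extract_complexes <- function(rxns) {
  if (inherits(rxns, "tcell_model")) rxns <- crn_reactions(rxns)
  if (length(rxns) == 0) return(character())
  unique(unlist(lapply(rxns, function(r) {
    c(complex_label(r$reactants), complex_label(r$products))
  })))
}

## Internal: exact rank of an integer matrix by fraction-free (Bareiss)
## Gaussian elimination. Avoids floating-point rank ambiguity.
integer_rank <- function(A) {
  A <- as.matrix(A)
  storage.mode(A) <- "double"   # exact for the small integers involved
  nr <- nrow(A)
  nc <- ncol(A)
  rank <- 0L
  row <- 1L
  prev <- 1
  for (col in seq_len(nc)) {
    if (row > nr) break
    piv <- which(A[row:nr, col] != 0)
    if (length(piv) == 0) next
    piv <- piv[1] + row - 1L
    if (piv != row) A[c(row, piv), ] <- A[c(piv, row), ]
    if (row < nr) {
      for (i in (row + 1L):nr) {
        A[i, ] <- (A[row, col] * A[i, ] - A[i, col] * A[row, ]) / prev
      }
    }
    prev <- A[row, col]
    rank <- rank + 1L
    row <- row + 1L
  }
  rank
}

#' One-line structural verdicts for a set of models
#'
#' @param ids Model ids to analyse.
#' @param params A [parameter_set()] used to build the networks (rates do
#'   not affect the structure).
#' @return A tibble with columns `model`, `name`, `n_complexes`,
#'   `linkage_classes`, `rank`, `deficiency`, `weakly_reversible`.
#' @export
crn_verdicts <- function(ids = 1:9, params = parameter_set()) {
  purrr::map_dfr(ids, function(id) {
    cs <- crn_structure(build_model(id, params))
    tibble::tibble(model = id, name = model_names[id],
                   n_complexes = cs$n_complexes,
                   linkage_classes = cs$linkage_classes,
                   rank = cs$rank, deficiency = cs$deficiency,
                   weakly_reversible = cs$weakly_reversible)
  })
}
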