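## Mass-action reaction-network machinery.
##
## A model is a list of irreversible reactions with integer stoichiometry
## (at most bimolecular in our networks). The ODE right-hand side and its
## Jacobian are generated from the reaction list, so the simulated dynamics
## and the structural (complex/deficiency) view always refer to the same
## object.

#' Construct a single mass-action reaction
#'
#' @param reactants,products Named numeric vectors of stoichiometric
#'   coefficients (nonnegative integers), e.g. `c(L = 1, R = 1)`.
#' @param rate Nonnegative rate constant.
#' @param name Symbolic name of the rate constant (for export and display).
#' @return A list of class `tcell_reaction`.
#' @export
reaction <- function(reactants, products, rate, name = deparse(substitute(rate))) {
  stopifnot(length(reactants) >= 1, length(products) >= 1)
  co <- c(reactants, products)
  if (any(co < 0) || any(co != round(co))) {
    stop("stoichiometric coefficients must be nonnegative integers")
  }
  if (!is.numeric(rate) || length(rate) != 1 || rate < 0) {
    stop("rate must be a nonnegative scalar")
  }
  structure(list(reactants = reactants, products = products,
                 rate = rate, name = name),
            class = "tcell_reaction")
}

## Internal: compile a reaction list over a species vector into index/matrix
## form used by the generated RHS and Jacobian. Reactions in our models have
## at most two reactant molecules (counting multiplicity).
compile_network <- function(species, reactions) {
  ns <- length(species)
  nr <- length(reactions)
  stoich <- matrix(0, ns, nr, dimnames = list(species, NULL))
  rx1 <- integer(nr)
  rx2 <- rep.int(ns + 1L, nr)  # ns+1 indexes a padded constant 1
  k <- numeric(nr)
  for (j in seq_len(nr)) {
    r <- reactions[[j]]
    if (!all(names(r$reactants) %in% species) ||
        !all(names(r$products) %in% species)) {
      stop("reaction ", j, " references unknown species")
    }
    idx <- rep(match(names(r$reactants), species), times = r$reactants)
    if (length(idx) > 2) stop("at most bimolecular reactions are supported")
    rx1[j] <- idx[1]
    if (length(idx) == 2) rx2[j] <- idx[2]
    stoich[names(r$reactants), j] <- stoich[names(r$reactants), j] - r$reactants
    stoich[names(r$products), j] <- stoich[names(r$products), j] + r$products
    k[j] <- r$rate
  }
  list(stoich = stoich, rx1 = rx1, rx2 = rx2, k = k)
}

## Internal: full-state derivative for a compiled network.
network_rhs <- function(compiled, x) {
  xa <- c(x, 1)
  rates <- compiled$k * xa[compiled$rx1] * xa[compiled$rx2]
  drop(compiled$stoich %*% rates)
}

## Internal: full-state Jacobian (ns x ns).
network_jacobian <- function(compiled, x) {
  ns <- nrow(compiled$stoich)
  nr <- length(compiled$k)
  xa <- c(x, 1)
  Jr <- matrix(0, nr, ns)
  i1 <- compiled$rx1
  i2 <- compiled$rx2
  d1 <- compiled$k * xa[i2]
  Jr[cbind(seq_len(nr), i1)] <- Jr[cbind(seq_len(nr), i1)] + d1
  has2 <- i2 <= ns
  if (any(has2)) {
    w <- which(has2)
    Jr[cbind(w, i2[w])] <- Jr[cbind(w, i2[w])] + compiled$k[w] * xa[i1[w]]
  }
  compiled$stoich %*% Jr
}

#' Evaluate the mass-action right-hand side of a model
#'
#' @param model A `tcell_model` from [build_model()].
#' @param state Named (or model-ordered) nonnegative state vector, counts
#'   per cell.
#' @return Named derivative vector, one entry per species.
#' @export
model_rhs <- function(model, state) {
  state <- as_model_state(model, state)
  stats::setNames(network_rhs(model$compiled, state), model$species)
}

#' Evaluate the Jacobian of the full system at a state
#'
#' @inheritParams model_rhs
#' @return A species-by-species matrix.
#' @export
model_jacobian <- function(model, state) {
  state <- as_model_state(model, state)
  J <- network_jacobian(model$compiled, state)
  dimnames(J) <- list(model$species, model$species)
  J
}

## Internal: coerce/validate a state vector against the model's species.
as_model_state <- function(model, state) {
  if (!is.null(names(state))) {
    if (!setequal(names(state), model$species)) {
      stop("state names do not match the model's species")
    }
    state <- state[model$species]
  }
  if (length(state) != length(model$species)) {
    stop("state has length ", length(state), ", expected ",
         length(model$species))
  }
  as.numeric(state)
}

#' Conserved quantities of a model evaluated at a state
#'
#' @inheritParams model_rhs
#' @return Named vector of the linear conserved quantities (total ligand,
#'   total receptor, and pool totals where present).
#' @export
conserved_quantities <- function(model, state) {
  state <- as_model_state(model, state)
  vapply(model$conserved, function(cq) {
    sum(cq$coef * state[match(names(cq$coef), model$species)])
  }, numeric(1)) |>
    stats::setNames(vapply(model$conserved, `[[`, "", "name"))
}

## ---- reduction by conservation ----------------------------------------

#' Reduce a model by eliminating one species per conserved quantity
#'
#' Each conserved quantity names an eliminated species (free ligand for
#' total ligand, free receptor for total receptor, the inactive pool
#' species for enzyme/output pools). The reduced system lives on the
#' compact set K where all original species are nonnegative; the mapping
#' back to the full state is exact.
#'
#' @param model A `tcell_model`.
#' @return A list with elements `kept` (species names of the reduced
#'   state), `to_full` (function from reduced to full named state),
#'   `rhs` (function of the reduced state), `jacobian` (function of the
#'   reduced state), `upper` (upper bounds of K's bounding box), and
#'   `model`.
#' @export
reduce_by_conservation <- function(model) {
  species <- model$species
  elim <- vapply(model$conserved, `[[`, "", "eliminate")
  totals <- vapply(model$conserved, `[[`, numeric(1), "total")
  if (any(totals < 0)) stop("conserved totals must be nonnegative (K is empty)")
  kept <- setdiff(species, elim)
  kidx <- match(kept, species)
  eidx <- match(elim, species)
  ## coefficient rows: elim_j = total_j - sum(coef_jk * kept_k); the
  ## eliminated species must carry coefficient 1 in its own law
  crows <- matrix(0, length(model$conserved), length(kept))
  for (i in seq_along(model$conserved)) {
    cq <- model$conserved[[i]]
    if (is.na(cq$coef[elim[i]]) || cq$coef[[elim[i]]] != 1) {
      stop("eliminated species must have coefficient 1 in its conserved quantity")
    }
    nm <- intersect(names(cq$coef), kept)
    crows[i, match(nm, kept)] <- cq$coef[nm]
  }
  to_full <- function(xr) {
    x <- numeric(length(species))
    x[kidx] <- xr
    x[eidx] <- totals - drop(crows %*% xr)
    stats::setNames(x, species)
  }
  rhs_red <- function(xr) network_rhs(model$compiled, to_full(xr))[kidx]
  jac_red <- function(xr) {
    J <- network_jacobian(model$compiled, to_full(xr))
    J[kidx, kidx, drop = FALSE] - J[kidx, eidx, drop = FALSE] %*% crows
  }
  ## bounding box of K: each kept species is bounded by the smallest
  ## total/coefficient ratio over the laws containing it
  upper <- vapply(seq_along(kept), function(i) {
    lims <- vapply(model$conserved, function(cq) {
      co <- cq$coef[kept[i]]
      if (is.na(co) || co == 0) Inf else cq$total / co
    }, numeric(1))
    min(lims)
  }, numeric(1))
  list(kept = kept, to_full = to_full, rhs = rhs_red, jacobian = jac_red,
       upper = stats::setNames(upper, kept), model = model)
}

## ---- export formats ----------------------------------------------------

#' Export a model's reactions as a plain-text reaction list
#'
#' One reaction per line, `"reactants -> products ; rate_name = value"`.
#'
#' @param model A `tcell_model`.
#' @param structural Use the structural (deficiency-analysis) network where
#'   the model defines one (models 4 and 9); default `FALSE`.
#' @return Character vector of lines.
#' @export
reaction_lines <- function(model, structural = FALSE) {
  rxns <- if (structural) crn_reactions(model) else model$reactions
  side <- function(v) {
    paste(ifelse(v > 1, paste0(v, " "), ""), names(v),
          sep = "", collapse = " + ")
  }
  vapply(rxns, function(r) {
    sprintf("%s -> %s ; %s = %.10g", side(r$reactants), side(r$products),
            r$name, r$rate)
  }, character(1))
}

#' Export a model's complex graph as an edge list
#'
#' @inheritParams reaction_lines
#' @return A tibble with columns `from`, `to`, `rate_name`, `rate` where
#'   `from`/`to` are canonical complex labels.
#' @export
reaction_edges <- function(model, structural = FALSE) {
  rxns <- if (structural) crn_reactions(model) else model$reactions
  lab <- function(v) {
    v <- v[order(names(v))]
    paste(ifelse(v > 1, paste0(v, " "), ""), names(v), sep = "", collapse = " + ")
  }
  tibble::tibble(
    from = vapply(rxns, function(r) lab(r$reactants), character(1)),
    to = vapply(rxns, function(r) lab(r$products), character(1)),
    rate_name = vapply(rxns, `[[`, "", "name"),
    rate = vapply(rxns, `[[`, numeric(1), "rate")
  )
}

## Internal: the network used for structural (deficiency) analysis.
crn_reactions <- function(model) {
  if (!is.null(model$crn)) model$crn else model$reactions
}
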