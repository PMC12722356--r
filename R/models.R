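## The nine phenotypic models of TCR activation, as explicit mass-action
## reaction networks. Chain states C_0 ... C_N are TCR-pMHC complexes with
## increasing numbers of completed proofreading modifications; C_N is the
## signalling-competent state.

model_names <- c(
  "occupancy",
  "kinetic proofreading",
  "KPR with limited signalling",
  "KPR with sustained signalling",
  "KPR with negative feedback",
  "KPR with stabilizing activation chain",
  "KPR with incoherent feed-forward loop",
  "KPR with limited signalling and IFF",
  "KPR with limited and sustained signalling"
)

#' Build one of the nine T-cell activation models
#'
#' Returns the model's reaction network together with its generated
#' mass-action ODE system, conserved quantities, designated response
#' readout, and (for the sustained-signalling models 4 and 9) the
#' structural network used for deficiency analysis.
#'
#' Model summaries (chain states C_0..C_N throughout, binding
#' `L + R -> C_0` at `kappa`, forward steps at `phi`, unbinding at
#' `v = 1/tau`):
#' \describe{
#'   \item{1 occupancy}{a single bound state; the readout is occupancy
#'     itself.}
#'   \item{2 KPR}{plain proofreading chain; readout C_N.}
#'   \item{3 limited signalling}{C_N converts to a non-signalling bound
#'     state C_{N+1} at `xi`; readout C_N.}
#'   \item{4 sustained signalling}{unbinding from C_N leaves an unbound,
#'     still-signalling receptor D that resets at `Omega` and rebinds
#'     ligand straight into C_N; readout C_N + D.}
#'   \item{5 negative feedback}{active SHP-1 (S), produced from an
#'     inactive pool by the first modified state C_1, adds `gamma * S` to
#'     the dephosphorylation rate of every step beyond the first; the
#'     first step reverts spontaneously at `b` only; readout C_N.}
#'   \item{6 stabilizing chain}{step-dependent rates
#'     `v(i) = v * r_off^(-i)` and `phi(i) = phi * r_phos^(i)`; readout
#'     C_N.}
#'   \item{7 IFF}{model 2 plus an incoherent feed-forward output layer:
#'     C_N activates Y, C_N deactivates the output X directly while Y
#'     activates it; readout X.}
#'   \item{8 limited signalling + IFF}{model 3 driving the same output
#'     layer; readout X.}
#'   \item{9 limited + sustained signalling}{both the `xi` branch and the
#'     sustained receptor D; readout C_N + D.}
#' }
#'
#' @param id Model id, 1 to 9.
#' @param params A [parameter_set()].
#' @return An object of class `tcell_model`.
#' @export
#' @examples
#' m <- build_model(3, parameter_set(L_T = 1e3, tau = 2, N = 2))
#' m$species
build_model <- function(id, params = parameter_set()) {
  if (!is.numeric(id) || length(id) != 1 || !(id %in% 1:9)) {
    stop("unknown model id: ", id, " (expected 1..9)")
  }
  stopifnot(inherits(params, "tcell_params"))
  id <- as.integer(id)
  p <- params
  cn <- p$constants
  N <- p$N
  chain <- paste0("C", 0:N)
  Cns <- paste0("C", N + 1)  # non-signalling bound state (limited signalling)

  rx <- list()
  add <- function(reactants, products, rate, name) {
    rx[[length(rx) + 1]] <<- reaction(reactants, products, rate, name)
  }

  bind <- function() add(c(L = 1, R = 1), c(C0 = 1), p$kappa, "kappa")
  fwd <- function(rates = rep(p$phi, N), names = rep("phi", N)) {
    for (i in seq_len(N)) {
      add(stats::setNames(1, chain[i]), stats::setNames(1, chain[i + 1]),
          rates[i], names[i])
    }
  }
  unbind <- function(states, rates, names) {
    for (i in seq_along(states)) {
      add(stats::setNames(1, states[i]), c(L = 1, R = 1), rates[i], names[i])
    }
  }

  species <- c("L", "R", chain)
  readout <- stats::setNames(1, chain[N + 1])
  crn <- NULL

  if (id == 1) {
    species <- c("L", "R", "C0")
    add(c(L = 1, R = 1), c(C0 = 1), p$kappa, "kappa")
    add(c(C0 = 1), c(L = 1, R = 1), p$v, "v")
    readout <- c(C0 = 1)
  } else if (id == 2) {
    bind(); fwd(); unbind(chain, rep(p$v, N + 1), rep("v", N + 1))
  } else if (id == 3) {
    species <- c(species, Cns)
    bind(); fwd()
    unbind(chain, rep(p$v, N + 1), rep("v", N + 1))
    add(stats::setNames(1, chain[N + 1]), stats::setNames(1, Cns), cn$xi, "xi")
    unbind(Cns, p$v, "v")
  } else if (id == 4) {
    species <- c(species, "D")
    bind(); fwd()
    unbind(chain[1:N], rep(p$v, N), rep("v", N))
    add(stats::setNames(1, chain[N + 1]), c(L = 1, D = 1), p$v, "v")
    add(c(L = 1, D = 1), stats::setNames(1, chain[N + 1]), p$kappa, "kappa")
    add(c(D = 1), c(R = 1), cn$Omega, "Omega")
    readout <- stats::setNames(c(1, 1), c(chain[N + 1], "D"))
    crn <- c(
      list(reaction(c(L = 1, R = 1), c(C0 = 1), p$kappa, "kappa")),
      lapply(seq_len(N), function(i) {
        reaction(stats::setNames(1, chain[i]), stats::setNames(1, chain[i + 1]),
                 p$phi, "phi")
      }),
      lapply(1:N, function(i) {
        reaction(stats::setNames(1, chain[i]), c(L = 1, R = 1), p$v, "v")
      }),
      list(reaction(stats::setNames(1, chain[N + 1]), c(D = 1), p$v, "v"),
           reaction(c(D = 1), c(L = 1, R = 1), cn$Omega, "Omega"))
    )
  } else if (id == 5) {
    species <- c(species, "S", "Si")
    bind(); fwd()
    unbind(chain, rep(p$v, N + 1), rep("v", N + 1))
    ## spontaneous dephosphorylation on every step
    for (i in seq_len(N)) {
      add(stats::setNames(1, chain[i + 1]), stats::setNames(1, chain[i]),
          p$b, "b")
    }
    ## SHP-1-mediated dephosphorylation on steps beyond the first: the
    ## first modification is protected, which closes the positive loop
    ## through C_1 that makes multiple steady states possible
    if (N >= 2) {
      for (i in 2:N) {
        add(stats::setNames(c(1, 1), c(chain[i + 1], "S")),
            stats::setNames(c(1, 1), c(chain[i], "S")), p$gamma, "gamma")
      }
    }
    add(c(C1 = 1, Si = 1), c(C1 = 1, S = 1), p$alpha, "alpha")
    add(c(S = 1), c(Si = 1), p$beta, "beta")
  } else if (id == 6) {
    bind()
    fwd(p$phi * cn$r_phos^(0:(N - 1)), sprintf("phi_%d", 0:(N - 1)))
    unbind(chain, p$v * cn$r_off^(-(0:N)), sprintf("v_%d", 0:N))
  } else if (id %in% c(7, 8)) {
    if (id == 8) species <- c(species, Cns)
    species <- c(species, "Y", "Yi", "X", "Xi")
    bind(); fwd()
    unbind(chain, rep(p$v, N + 1), rep("v", N + 1))
    if (id == 8) {
      add(stats::setNames(1, chain[N + 1]), stats::setNames(1, Cns),
          cn$xi, "xi")
      unbind(Cns, p$v, "v")
    }
    CN <- chain[N + 1]
    add(stats::setNames(c(1, 1), c("Yi", CN)),
        stats::setNames(c(1, 1), c("Y", CN)), cn$sigma_act, "sigma")
    add(c(Y = 1), c(Yi = 1), cn$iff_a, "a_iff")
    add(c(Xi = 1), c(X = 1), cn$iff_c, "c_iff")
    add(c(Xi = 1, Y = 1), c(X = 1, Y = 1), cn$delta_act, "delta")
    add(c(X = 1), c(Xi = 1), cn$iff_d, "d_iff")
    add(stats::setNames(c(1, 1), c("X", CN)),
        stats::setNames(c(1, 1), c("Xi", CN)), cn$mu_inh, "mu")
    readout <- c(X = 1)
  } else if (id == 9) {
    species <- c(species, Cns, "D")
    bind(); fwd()
    unbind(chain[1:N], rep(p$v, N), rep("v", N))
    add(stats::setNames(1, chain[N + 1]), c(L = 1, D = 1), p$v, "v")
    add(c(L = 1, D = 1), stats::setNames(1, chain[N + 1]), p$kappa, "kappa")
    add(stats::setNames(1, chain[N + 1]), stats::setNames(1, Cns), cn$xi, "xi")
    unbind(Cns, p$v, "v")
    add(c(D = 1), c(R = 1), cn$Omega, "Omega")
    readout <- stats::setNames(c(1, 1), c(chain[N + 1], "D"))
    crn <- c(
      list(reaction(c(L = 1, R = 1), c(C0 = 1), p$kappa, "kappa")),
      lapply(seq_len(N), function(i) {
        reaction(stats::setNames(1, chain[i]), stats::setNames(1, chain[i + 1]),
                 p$phi, "phi")
      }),
      lapply(1:N, function(i) {
        reaction(stats::setNames(1, chain[i]), c(L = 1, R = 1), p$v, "v")
      }),
      list(reaction(stats::setNames(1, chain[N + 1]), c(D = 1), p$v, "v"),
           reaction(c(D = 1), c(L = 1, R = 1), cn$Omega, "Omega"),
           reaction(stats::setNames(1, chain[N + 1]), stats::setNames(1, Cns),
                    cn$xi, "xi"),
           reaction(stats::setNames(1, Cns), c(L = 1, R = 1), p$v, "v"))
    )
  }

  ## conserved quantities: each names the species eliminated in the
  ## reduced system (coefficient 1, appearing in no other law)
  bound <- setdiff(species, c("L", "R", "D", "S", "Si", "Y", "Yi", "X", "Xi"))
  lig_coef <- stats::setNames(rep(1, 1 + length(bound)), c("L", bound))
  rec_species <- c("R", bound, intersect("D", species))
  rec_coef <- stats::setNames(rep(1, length(rec_species)), rec_species)
  conserved <- list(
    list(name = "L_T", coef = lig_coef, total = p$L_T, eliminate = "L"),
    list(name = "R_T", coef = rec_coef, total = p$R_T, eliminate = "R")
  )
  if ("S" %in% species) {
    conserved <- c(conserved, list(list(
      name = "S_T", coef = c(S = 1, Si = 1), total = p$S_T, eliminate = "Si")))
  }
  if ("Y" %in% species) {
    conserved <- c(conserved, list(
      list(name = "m_total", coef = c(Y = 1, Yi = 1),
           total = cn$m_total, eliminate = "Yi"),
      list(name = "l_total", coef = c(X = 1, Xi = 1),
           total = cn$l_total, eliminate = "Xi")
    ))
  }

  ## resting (unbound) initial state: all receptor free, pools inactive
  init <- stats::setNames(numeric(length(species)), species)
  init["L"] <- p$L_T
  init["R"] <- p$R_T
  if ("Si" %in% species) init["Si"] <- p$S_T
  if ("Yi" %in% species) init["Yi"] <- cn$m_total
  if ("Xi" %in% species) init["Xi"] <- cn$l_total

  structure(list(
    id = id,
    name = model_names[id],
    species = species,
    reactions = rx,
    compiled = compile_network(species, rx),
    conserved = conserved,
    readout = readout,
    params = params,
    crn = crn,
    init = init
  ), class = "tcell_model")
}

#' @export
print.tcell_model <- function(x, ...) {
  cat("<tcell_model ", x$id, ": ", x$name, ">\n", sep = "")
  cat("  species (", length(x$species), "): ",
      paste(x$species, collapse = ", "), "\n", sep = "")
  cat("  reactions: ", length(x$reactions),
      "; conserved: ", paste(vapply(x$conserved, `[[`, "", "name"),
                             collapse = ", "), "\n", sep = "")
  cat("  readout: ", paste(names(x$readout), collapse = " + "), "\n", sep = "")
  invisible(x)
}

#' Response readout of a model at a state
#'
#' @inheritParams model_rhs
#' @return Scalar readout value (counts per cell).
#' @export
model_readout <- function(model, state) {
  state <- as_model_state(model, state)
  sum(model$readout * state[match(names(model$readout), model$species)])
}
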