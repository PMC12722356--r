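---
title: "Phenotypic models of T-cell activation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotypic models of T-cell activation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcellkpr)
```

## The scientific problem

T cells recognise peptide-MHC ligands (pMHC) through the T-cell receptor
(TCR) and must distinguish rare, long-lived foreign ligands from an excess
of short-lived self ligands. `tcellkpr` implements and compares nine
phenotypic mass-action models of this decision: the occupancy model,
kinetic proofreading (KPR), and KPR extended with limited signalling,
sustained signalling, SHP-1 negative feedback, a stabilizing activation
chain, incoherent feed-forward (IFF) output layers, and the combination of
limited and sustained signalling. For each model the package asks: does
the steady-state response show an optimum in ligand dose or in
dissociation time, how do potency (EC50) and maximal response (Emax)
depend on bond lifetime, which parameters drive the output, and how many
steady states can coexist?

All models are chains of bound receptor states `C_0 ... C_N`. Ligand L and
receptor R bind at rate `kappa` (per molecule per second), the complex
advances by one proofreading step at the phosphorylation rate `phi`
(1/s), and every bound state unbinds at `v = 1/tau`, where `tau` is the
mean dissociation time of the bond. Unbinding resets all modifications,
which is what filters short-lived ligands. The response readout is the
occupancy of the signalling-competent state `C_N` (plus, where present,
the unbound receptor that continues to signal); for the IFF models it is
the downstream output X.

## Model definitions and the choices behind them

Every model is stored as an explicit list of mass-action reactions; the
ODE right-hand side, its Jacobian, the conserved quantities and the
structural (complex/deficiency) view are all generated from the same
reaction list, so there is no possibility of the simulated dynamics and
the analysed network drifting apart. All models conserve total ligand
`L_T` and total receptor `R_T`; the feedback and IFF models additionally
conserve their enzyme and output pools. Because every species carries a
nonzero coefficient in at least one conserved quantity, the dynamics live
on a compact invariant set and the reduced system (one species eliminated
per conserved quantity) has no neutral directions, which is what makes
the steady-state and stability analysis clean.

Three wirings deserve explanation because the published closed-form
responses do not fully determine them.

**Sustained signalling (models 4 and 9).** Unbinding from `C_N` releases
the ligand and leaves an unbound receptor D that continues to signal,
resets to baseline at `Omega` (1/s), and — crucially — rebinds free
ligand directly back into `C_N`. With this wiring the steady-state
response `C_N + D` reproduces the closed form
`(kappa L + v + Omega) / (Omega + a^N kappa L) * a^N * C_T`
(with `a = phi/(phi+v)`, `C_T` the equilibrium total bound complexes and
`L` the free ligand) to machine precision, including `E_max = R_T`:
at saturating dose, rebinding prevents the sustained receptor from ever
resetting, so the entire receptor pool ends up signalling. For model 9
the same derivation forces a denominator
`a^N kappa L v + Omega v + xi kappa L + xi Omega`; the corresponding
expression with `a^N kappa L` in place of `a^N kappa L v` is
dimensionally inhomogeneous and disagrees with the model-4 limit at
`xi = 0`, so the package uses the homogeneous form throughout.

For the deficiency analysis these two models carry a separate structural
network in which the sustained receptor is bookkept as still
ligand-associated (complexes `{L+R, C_0, ..., C_N, D}`, reset
`D -> L + R`). In that representation the networks are weakly reversible
with deficiency zero, which is the structural basis of the uniqueness
result; the quantitative network additionally resolves free-ligand
exchange at D (the reset reaction `D -> R` alone can never sit on a
directed cycle, so no mass-action realization of the quantitative
dynamics is weakly reversible). Both views are exported
(`crn_structure(..., structural = FALSE)` analyses the simulated
network), and the package treats the structural view as the one the
uniqueness argument refers to.

**Negative feedback (model 5).** Active SHP-1 (S) is produced from an
inactive pool `S_T - S` at rate `alpha * C_1` — the first modified state
is the kinase-proximal species that recruits the phosphatase — and decays
at `beta`. Each proofreading step reverts spontaneously at `b`; the steps
beyond the first additionally revert at `gamma * S`, while the first
step is not a substrate of SHP-1. Protecting the first step is the
biologically natural way to close a positive loop: strong feedback piles
complexes up in `C_1`, which activates more SHP-1. With feedback acting
uniformly on every step the `C_1` occupancy share moves by under 3% over
the whole feedback range, far too little gain for multistability, and the
model is monostable throughout the scanned parameter box; the
protected-first-step wiring produces exactly three positive steady
states (two stable, one unstable) inside the box, which is the
behaviour this model family is known for. Because every bound state
still unbinds at `v`, total binding remains `C_T`, and the model's EC50
keeps the `K_D + R_T/2` form.

At steady state the problem reduces exactly to a scalar balance for S
(chain occupancies are a linear solve given S). The package uses this
reduction as an independent cross-check of the multistart root counts,
never as the primary search method.

**IFF output layer (models 7 and 8).** The signalling state `C_N`
activates an intermediate Y from a pool of `m_total = 100` molecules at
`sigma = 0.5` per molecule per second (deactivation `a = 1`/s), while
the output X (pool `l_total = 100`) is activated basally at `c = 1`/s
and by Y at `delta = 50`, and deactivated basally at `d = 500`/s and by
`C_N` at `mu = 2.5`. The steady-state output is then exactly
`X = l (c + delta Y) / (c + d + delta Y + mu C_N)`, the published form
(the `C_N`-inhibition term carries `1/c`; the variant with `1/d` printed
for the plain-IFF response row is inconsistent with that model's own
E_max row and with the limit relating the two IFF models, so `1/c` is
used for both). The source constant `b = 500`/s does not enter the
steady-state response and is retained in `model_constants()` for
completeness only.

**Stabilizing chain (model 6).** Later chain states are more stable and
phosphorylate faster: `v(i) = v * r_off^(-i)` with `r_off = 1.5` and
`phi(i) = phi * r_phos^i` with `r_phos = 1.03`. The chain occupancy
profile is dose-independent, so the response is a fixed fraction
`delta_stab` of an effective total-complex curve whose dissociation
constant uses the occupancy-weighted mean unbinding rate; both composites
are computed from the chain recursion, not fitted.

## Parameters

The eight shared parameters come from four literature sources; the
package stores the per-source table (`source_table()`) and derives mean,
maximum and minimum columns by aggregating over the sources that report
each parameter (three report the phosphatase efficiency, two the SHP-1
activation and deactivation rates). Means are kept at full precision
internally; displayed values follow the sources' rounding. Units: counts
per cell for totals, per second for first-order rates, per molecule per
second for bimolecular rates.

Two conventions matter everywhere:

* `tau` (seconds) is the user-facing kinetic variable; the unbinding
  rate is always derived as `v = 1/tau`.
* The proofreading depth defaults to `N = 5` steps — a conventional
  choice, recorded in every parameter set and configurable in every
  function, since the comparative analysis does not fix it.

## Numerical methods

*Integration.* `simulate_model()` integrates the full system with lsoda
(default `rtol = 1e-8`, `atol = 1e-10`) using the analytic Jacobian
generated from the reaction list. Conservation holds to 1e-8 relative
along trajectories and states stay nonnegative up to integration
tolerance.

*Steady states.* `find_steady_states()` runs damped Newton iterations on
the reduced system from seeded uniform starts in the bounding box of the
invariant set (200 by default; the resting state and the box centre are
always included), deduplicates converged roots at 1e-6 relative
distance, verifies interiority, and classifies stability by the
eigenvalues of the reduced Jacobian with a `1e-9` marginality threshold
on real parts — wide enough to absorb floating noise at the problem's
scales, narrow enough not to mask genuine neutral directions. The
multistability scan covers `phi` in [0.535, 1], `tau` in [0.5, 20] s and
`L_T` in [1e2, 1e5] (5 x 6 x 7 grid by default); the three-steady-state
region of model 5 is a narrow wedge around the high-`phi`, long-`tau`,
low-dose corner of this box, so scans at much coarser density will miss
it.

*Responses.* `numeric_response()` solves for the steady state by Newton
from deterministic starts with an integrate-then-polish fallback. For
model 5, which can be bistable, the response is defined as the state
reached by forward integration from the resting, fully unbound initial
condition — the biological resting state; the integration is staged and
a Newton polish is only accepted once it agrees with the trajectory's
current position, so the selection rule cannot jump basins.
`analytic_response()` evaluates the closed forms; for models 5-8 the
composites (`r_plus`/`r_minus`, `delta_stab`, `Y_ss`) are computed
numerically from the models' own steady-state structure rather than
reproduced symbolically, and the agreement between the two routes is a
tested contract (1e-6 relative for the fully specified models over a
7 x 7 dose/tau log grid).

*Dose metrics.* `emax_ec50()` takes `E_max` as the supremum over a
200-point log dose grid (1e-1 to 1e7 molecules/cell by default),
automatically extending the grid decade by decade until the top decade
varies by under 1% (saturating curves) and treating bell-shaped curves
by their peak; `EC_50` is located on the rising branch by bisection to
1e-4 relative dose accuracy, with the branch recorded.

*Feature classification.* Optima and modes use a 1% relative prominence
threshold — below figure-reading precision, above floating noise; every
verdict records the threshold. Dissociation-time optima are assessed on
the standard 0.1-100 s window; mode counting uses 0.1-1e4 s because the
second mode of the limited-signalling IFF model sits beyond 100 s at the
doses where it is prominent. Probe doses are model-relative: one tenth
of the model's own EC50, ten times it, and the location of the interior
dose optimum where one exists. Verdicts are invariant under doubling the
grid density (tested).

*Sensitivity.* `run_prcc_study()` draws a Latin hypercube over the
literature min-max ranges (log-uniform for the wide-ranged association
rate, phosphatase efficiency and SHP-1 deactivation rate, and for the
model constants, which the sources give as single values and the package
spans over a factor of ten either way), evaluates the numeric response
at the study conditions `L_T = 1e3` molecules/cell and `tau = 2` s, and
computes partial rank correlation coefficients via the precision matrix
of the rank correlations (with an explicit residual-projection fallback
for degenerate designs). The implementation is tested to 1e-10 against a
brute-force rank-residual oracle. Failed solver rows are dropped up to a
1% cap; beyond that the study aborts rather than risk censoring bias.
The packaged studies use n = 2000 rows and three seeds; the sign
structure is stable across seeds at this size.

## What the synthetic scenarios do and do not show

`paper_scenarios()` enumerates the full study grid (nine models, three
parameter columns, dose and dissociation-time sweeps, the model-5 scan
and nine PRCC studies); `fuzz_scenarios()` draws random parameter sets
inside the literature boxes for property-based tests. These inputs
emulate the study conditions, not wet-lab data: there is no measurement
noise, no ligand heterogeneity, no spatial or mechanical effect. Passing
tests therefore establish that the implementation reproduces the models'
mathematical behaviour under the published parameter ranges — not that
the models describe any particular experiment.

## Known limitations

* The steady-state dose responses of the sustained-signalling models
  (4 and 9) are provably monotone in dose for every wiring consistent
  with their closed forms (the free-ligand correction to `C_T` cancels
  the apparent overshoot term exactly), so the package's feature matrix
  reports no interior dose optimum for them, and `E_max = R_T` is
  approached from below.
* Multistability searches are multistart methods: counts are exact only
  up to the coverage of the 200 seeded starts. For model 5 the scalar
  SHP-1 balance provides an independent count; for hypothetical models
  with more intricate root structure no such certificate exists.
* The composite constants entering the model-5 and model-6 closed forms
  are represented by numerically computed equivalents; symbolic forms
  are not reproduced.
* No stochastic (Gillespie), spatial, or force-dependent (catch-bond)
  variants; the networks are well-mixed deterministic ODEs throughout.

## Reproducing the study

`reproduce_study(out_dir)` runs every stage end to end and writes tidy
CSVs plus a checksummed manifest; `scripts/acceptance.R` (in the source
repository) recomputes the headline numbers from scratch and writes them
as JSON. Both are deterministic given their seeds.
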