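---
title: "Context-specific genome-scale models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-specific genome-scale models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gemtailor)
```

This vignette explains what the package computes, which assumptions those
computations rest on, which knobs matter, and where the genuinely open
design choices were decided. It states no empirical result that the test
suite or the acceptance script does not itself compute.

## 1. The modelling framework

A genome-scale metabolic model (GEM) is a stoichiometric network: a matrix
$S \in \mathbb{R}^{m \times n}$ over $m$ compartment-resolved metabolites
and $n$ reactions, flux bounds $l, u$ (mmol·gDW⁻¹·h⁻¹ by convention), a
biomass pseudo-reaction draining precursors in fixed proportions, and
boolean gene–protein–reaction (GPR) rules linking genes to reactions.
Flux balance analysis (FBA) assumes a metabolic pseudo-steady state
($Sv = 0$: every internal metabolite's production balances its
consumption) and maximizes the biomass flux by linear programming. The
steady-state assumption is the load-bearing one: it reduces kinetics to
capacities, which is what makes genome-scale analysis tractable, and it is
also why all downstream quantities (flux-sums, fold-changes) describe
*throughput*, not concentrations.

FBA optima are usually degenerate. For reproducible flux vectors,
`fba_min_norm()` selects the optimum of minimal squared Euclidean norm.
Rather than subtracting a scaled $\lVert v \rVert^2$ from the objective in
one solve, the implementation is two-stage: an LP for $Z^*$, then a QP
minimizing $\lVert v\rVert^2$ subject to $c^\top v \ge Z^*(1 - 10^{-6})$.
At that magnitude the two formulations coincide to well within every
tolerance used here, and the two-stage form is numerically stabler. The
QP is strictly convex, so the regularized flux distribution is unique —
the basis of the pipeline's determinism guarantee.

## 2. Tailoring with GIMME

GIMME turns one context's expression into a context-specific sub-model:

1. Map gene values to reactions through GPRs: `and` → min (an enzyme
   complex is limited by its scarcest subunit), `or` → max (the best
   isozyme suffices). The underlying study does not state its rule; this
   is the GIMME-literature default. Reactions without a GPR (transporters,
   drains) are *absent*, never zero — absence of evidence is not low
   expression.
2. Penalty weights $x_j = \max(0,\, x_{\text{thr}} - x_j^{\text{expr}})$;
   absent reactions get weight 0 and are never penalized.
3. Minimize $\sum_j x_j\lvert v_j\rvert$ subject to steady state, the
   model bounds, and a biomass floor of 90% of the *parent* model optimum
   ($\lvert v \rvert$ via non-negative splitting of reversible reactions,
   both directions carrying the same weight).
4. Keep every weight-0 reaction plus the penalized reactions that still
   carry flux ($\lvert v\rvert > 10^{-9}$; these are the *reinserted*
   set); remove the rest and prune orphaned metabolites.

The extracted model is re-checked by FBA to attain the floor; failure
would indicate a tolerance misconfiguration, not a modelling outcome, and
raises an internal error.

### Threshold calibration

One expression threshold is shared by all days and conditions. It is
defined as a quantile of the pooled reaction-mapped values over *all*
contexts (pooling gene-level values instead is available via
`pool = "gene"` but is not the default; which population the original
study pooled is not stated). The quantile convention is sorted-array
linear interpolation (R's type 7), recorded in the run report.

The quantile grid (default 0.70–0.90, step 0.01) is swept; each
candidate's 26 context models are tailored and their FBA biomass optima
form a simulated trajectory. "Most similar to the observed growth" is not
a defined metric in the source study, so the package states one: Pearson
correlation between the simulated biomass series and the observed
fresh-weight increase rate, concatenated over conditions (alphabetical
order, days ascending), with the rate over $(d{-}1, d]$ attributed to day
$d$. Ties are broken by RMSE after min–max scaling of both series, then by
the smaller quantile. Correlation is scale-free — appropriate because
model biomass flux and g/day are never unit-converted (the comparison is
of *patterns*, as in the source study); the min–max-scaled RMSE tie-break
resolves plateaus where several thresholds induce identical partitions.

### Why the synthetic pipeline does not strip constraints

`strip_constraints()` implements the published preprocessing for a
downloaded GEM: preset (photosynthesis-condition) bounds are replaced by
$[0, \infty)$ / $(-\infty, \infty)$. Whether the 90% floor then refers to
the stripped parent's optimum is an open point in the source; this package
uses the stripped parent by default. For the bundled synthetic scenario,
however, the toy model's bounds *are* the nutrient medium (finite glucose
and ammonium supply); stripping them would make the parent optimum run
into the artificial finite "infinity" and void the calibration. The
scenario config therefore sets `strip_constraints = FALSE`. Both behaviors
are config-switchable and recorded in the manifest.

## 3. Comparative stage

Flux magnitudes $\lvert v\rvert$ (not signed fluxes — ratios of signed
values are ill-defined under direction reversal; reversals are reported in
a sidecar table) are assembled into a contexts × reactions matrix; absent
reactions are imputed with one-tenth of the smallest positive entry of the
whole matrix (the "minimum" is global and computed in a single pass), and
zero fluxes of *present* reactions are floored to the same value so that
every log2 drought/control ratio is finite — a deliberate extension of the
published missing-value rule, flagged per cell. Items with
$\lvert\log_2 FC\rvert \ge 1$ on at least one day (the boundary is
inclusive: a ratio of exactly 2 counts) are clustered by average-linkage
agglomeration on distance $1 - r$, cut at 0.5. Constant profiles, whose
correlation is undefined, become singleton clusters. Cluster labels are
ordered by size then first member id; they carry no meaning beyond
membership. The same machinery runs on metabolite flux-sums
($\tfrac12\sum_j \lvert s_{ij}v_j\rvert$, equal to total influx at steady
state).

## 4. Numerical choices

- **Infinity encoding**: LP/QP solvers need finite bounds; `Inf` becomes
  $\pm 10^6$ (`GEM_BIG`), far above any attainable flux here. An "optimal"
  objective at $\ge 1\%$ of that magnitude is reported as `unbounded`.
- **LP solver**: a built-in dense two-phase simplex with Bland's rule —
  deterministic, cycle-proof, and exact to round-off at these problem
  sizes (≤ a few hundred variables). No external LP backend is required
  (none is available in the reference environment).
- **QP**: `quadprog`, after eliminating $Sv=0$ by an orthonormal
  null-space basis of $S$. The reduction keeps the Hessian perfectly
  conditioned and sidesteps active-set failures on models whose dead-end
  reactions are pinned to zero by the equalities; constraint columns that
  project to zero (blocked reactions) are vacuous and dropped.
- **Zero tolerance** for "carries flux": $10^{-9}$, shared between the
  reinsertion rule and flux reporting.
- **Screen tolerance**: "same biomass as the drought model" uses relative
  $10^{-6}$ (the source states none). If control and drought biomass
  already agree, the screen is degenerate — every no-effect deletion would
  "match" — and is reported as such with no candidates.
- **Deletion of the objective reaction** is included in the screen (it is
  trivially lethal) for completeness.

## 5. The synthetic scenario: what it emulates, and what a green test means

`generate_scenario()` builds a stated world mirroring the *design* of a
progressive-drought study: 13 days × {control, drought} × 4 replicates,
log-scale expression with additive Gaussian replicate noise (σ = 0.3; the
real microarray error structure is deliberately not modelled), a
compartmentalized toy GEM (cytosol, plastid, mitochondrion, peroxisome,
extracellular; 52 reactions), and a growth table with constant control
rate and a drought rate dropping to 40% after day 10. Planted features:

- a **key reaction** (`GDH_c`, a glutamate-dehydrogenase analogue) whose
  gene clears the threshold only in control days 12–13;
- a constitutive glutamate route `GS1_c` (capacity 4.95) expressed until
  day 10 and a stress-era isoform `GS2_c` (capacity 4.55) expressed from
  day 11 — so context biomass optima step 4.95 → 4.55 (late drought) and
  4.95 → 5.0 (late control, nitrogen-limited once the key reaction is in);
- **parallel glycolysis** in cytosol and plastid with the cytosolic branch
  transcriptionally shut down in late drought (flux rerouting with large
  fold-changes);
- late-drought-induced **flavonoid** and **photorespiration-like**
  branches that enter the drought models but carry no steady-state flux —
  model-content signal without flux signal, as in real GEMs whose biomass
  equation omits secondary metabolites;
- expression **tiers** (3.5 / 4.5–5.0 / 6.2 / 9.0) with counts arranged so
  that the active/inactive boundary of the pooled reaction-level
  distribution sits exactly at quantile 0.83: below it the suppressed tier
  stays active (no drought dip in simulated biomass), above it the
  threshold only nibbles into the active tier without changing any
  biomass value, so 0.83 is the smallest quantile attaining the best
  growth match and the sweep's tie-break selects it.

Two capacity facts were revised once during design, before freezing: the
drought dip must be large and the control-late rise small (otherwise the
observed flat control rate penalizes the true partition), and the plastid
translocator must not bottleneck carbon (otherwise inserting the key
reaction cannot restore the full control optimum). One structural fact is
*forced* by GIMME's 90% floor and worth knowing when reading the tests:
each alternative glutamate route must individually reach 90% of the parent
optimum for its context to tailor cleanly, so any two of them together
saturate the nitrogen limit — hence removing the key reaction from the
*parent* model does not lower its optimum; key-sensitivity is a property
of the late-day *context* models (which is also where the corresponding
published experiment operates).

A green synthetic run therefore establishes that the machinery — mapping,
thresholding, penalty LP, extraction, calibration, screens, comparative
stage — does what it claims on data whose answer is known. It does not
establish anything about real transcriptome noise structure, genome-scale
numerics (thousands of reactions), annotation quality of real GPRs, or the
biological validity of the 90% floor.

## 6. Known limitations

- The simplex and the dense matrices are sized for teaching-scale and
  mid-scale models; a genome-scale model with thousands of reactions wants
  a sparse revised simplex or an external solver behind the same API.
- GIMME is the only tailoring family implemented; iMAT/INIT-style
  comparisons are out of scope.
- SBML support covers Level 2 COBRA-style documents and the Level 3 fbc
  subset actually used by the targeted model files (bounds, objectives,
  gene associations; subsystems are probed from notes, not the groups
  extension). The writer emits Level 2.
- No flux variability analysis, no double deletions, no thermodynamic
  constraints; fold-changes inherit the fill rule's floor, so ratios
  involving filled cells are bounded, not exact.
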