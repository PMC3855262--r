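---
title: "Methods: inferring biomass composition from knockout phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring biomass composition from knockout phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model, the optimization problems, the default
parameters, and the numerical choices behind `qbiomass`. Code chunks are
illustrative and not evaluated at build time (the pipeline requires the
GLPK `glpsol` binary).

## Model and assumptions

A metabolic network is a stoichiometric matrix $S$ over metabolites and
reactions, flux bounds $l \le v \le u$, and per-reaction gene–protein–
reaction (GPR) boolean rules. The steady-state assumption $S v = 0$ with
bounds defines the feasible flux cone. A gene knockout disables every
reaction whose GPR evaluates false after removing the deleted genes; a
media condition closes all exchange uptakes and reopens the listed ones.

The data are *qualitative* phenotypes: each experiment is a set of deleted
genes, a media condition, and an observation `G` (growth) or `NG`
(no growth). The inference target is the set of biomass components — the
metabolites whose simultaneous net production the model should require for
growth. No quantitative coefficients are inferred; the published composition
uses a uniform magnitude (`coefficient = 2e-4` per component) purely to keep
biomass flux on a convenient scale.

Key assumptions:

* Steady state with no dilution terms; a metabolite "is producible" iff a
  sink on it can carry at least `v_min` flux while $S v = 0$ holds.
* Phenotypes are explained by *blocked biomass precursors*: an `NG` mutant
  fails because at least one biomass component became unproducible, a `G`
  mutant requires that none did.
* Observations may be noisy or outside the model scope, so the objective is
  maximum weighted *agreement*, not hard feasibility.

## Pipeline and optimization problems

### 1. Net-production-blocked metabolites

`prepare_for_blocking()` removes predefined biomass reactions (they must not
act as hidden drains) and adds a sink `SK_m` (bounds $[0, M]$) for every
metabolite. `producible_set_milp()` then solves

$$\max \sum_i z_i \quad \text{s.t. } S v = 0,\; l \le v \le u,\;
v_{\min} z_i \le x_i \le M z_i,\; z_i \in \{0,1\}$$

where $x_i$ is the sink flux of metabolite $i$. Metabolites with $z_i = 0$
are *blocked*. A per-metabolite LP (`producible_oracle()`) maximizing each
sink individually is the reference implementation; the test suite certifies
the two agree exactly on seeded random networks. Members of closed internal
cycles are correctly blocked even though internal cycle flux is feasible:
blocking is about *net* production through the sink, not internal activity.

`candidate_blocked()` is the difference `blocked(mutant) \ blocked(wild
type)`: the metabolites this knockout newly prevents the cell from making.

### 2. Include/exclude lists

`build_lists()` maps every retained experiment to its candidate set: an
include list for `NG`, an exclude list for `G`. Experiments whose candidate
set exceeds `filter_max` (default 100) are filtered out as uninformative
(a lesion that blocks half the metabolome says little about the biomass).
Replicated experiments merge into integer weights.

### 3. Agreement integer program

With binaries $m_i$ (metabolite $i$ in the biomass), $n_e$, $g_e$
(experiment $e$ reconciled):

$$\max \sum_e w_e (n_e + g_e) \quad \text{s.t.}\quad
n_e \le \sum_{i \in In(e)} m_i, \qquad
g_e \le 1 - m_i \;\; \forall i \in Ex(e).$$

`select_de_novo()` fixes the optimal agreement and re-minimizes the
component cost: uniform cost (minimum cardinality, `scheme = "minimal"`) or
preference-weighted (`scheme = "weighted"`, preferred metabolites cost
$-1$). Prior compositional knowledge enters as soft pseudo-experiments
(`em`, weight `em_weight`). `modify_biomass()` is lexicographic: maximize
agreement, then minimize removals from the predefined set $\mu$, then
minimize additions.

**Tie-breaking.** Alternative optima are common. Both selectors finish with
a greedy *pin-to-1* scan over candidates in sorted metabolite-id order:
include a metabolite iff an optimum containing everything pinned so far
plus this metabolite exists. This yields the lexicographically smallest
optimal set and makes results independent of input row order. (A pin-to-0
scan would yield the lexicographically *largest* set.)

### 4. Alternatives and essential precursors

`enumerate_alternatives()` re-solves with one component excluded and its
replacement forced, collecting swap-equivalent metabolites;
`essential_precursors()` tests, on robust media (componentwise union of all
tested conditions, `robust_media()`), which candidates are unavoidable
precursors of the proposal. A proposal is therefore an equivalence class.

### 5. Dead-end by-product repair

A composition chosen from blocked-metabolite evidence may force by-products
that nothing consumes; plain FBA then predicts `NG` for experiments the IP
reconciled. `deadend_byproducts()` keeps sinks on all metabolites, pins the
biomass flux to `eps`, and minimizes the number of active sinks via
indicator rows $x_i \le s_i$, $s_i \in \{0,1\}$. `augment_biomass()` adds
the union of active sinks (tagged `sink_role`, not evidence-supported
components) and iterates to a fixed point.

### 6. Growth prediction

`predict_growth_all()` scores the final composition by FBA: biomass flux
above `growth_flux_threshold` (default `1e-6`) predicts `G`.
`agreement_report()` tabulates agreement per media condition.

## Defaults and rationale

| parameter | default | rationale |
|---|---|---|
| `v_min` | `5e-4` | minimum sink flux that counts as net production; well above solver feasibility tolerance, well below typical bounds |
| big-$M$ / sink upper bound | `1000` | matches the default reaction bound magnitude, keeps the linking rows numerically mild |
| `filter_max` | `100` | drops experiments whose lesions are globally catastrophic rather than biomass-informative |
| `coefficient` | `2e-4` | per-component biomass stoichiometry; predictions are scale-invariant, see below |
| `eps` (dead-end) | `0.001` | demanded biomass flux during repair |
| `growth_flux_threshold` | `1e-6` | separates numerically zero from genuinely positive biomass flux |
| fitness threshold | `-1` | phenotype TSVs with numeric fitness classify `> -1` as `G`, `< -1` as `NG`; exact ties classify `G` with a message |

## Numerical choices

* **Solver.** All problems are written in CPLEX LP format and solved with
  `glpsol`. Pure LPs run with `--nopresol` so infeasibility is reported
  definitively. The objective row names every structural column, pinning
  the column order in the solution file.
* **Dead-end rescaling.** `glpsol`'s absolute integrality tolerance is
  `1e-5` and is not settable from the CLI. With `coefficient = 2e-4` and
  `eps = 1e-3` a forced by-product flux would be `2e-7` — below tolerance,
  so the MILP would accept infeasible relaxations. Because the constraint
  system is homogeneous, the detection problem is solved with a
  *unit-coefficient* biomass pinned at flux exactly `eps`: the active-sink
  sets are identical by scaling, and every demanded flux is `~1e-3`, far
  above tolerance. Growth prediction itself is likewise scale-invariant in
  `coefficient` (tested).
* **Determinism.** Given identical inputs and seed, every stage is
  deterministic: the tie-break direction is fixed, candidate sets are kept
  in sorted order, and the fixture generator restores the RNG state.

## Synthetic fixture generator: scope and limits

`make_random_network(fixture_spec(...))` assembles networks from linear
pathways (optionally sharing intermediates), isozyme pairs, parallel routes,
closed internal cycles, and by-product couplings, plants a biomass of
`planted_biomass_size` producible metabolites, and `plant_phenotypes()`
derives noiseless or noisy knockout phenotypes from it. All reactions the
generator emits are irreversible, which is what makes the test-suite's
reachability-closure oracle valid there; the package itself handles
reversible reactions (they are standard in loaded SBML/JSON models and are
covered by the solver and I/O tests). Typical acceptance sizes: 20–60
reactions for solver cross-validation, ~250 genes / 200 knockouts for
planted-biomass recovery; MILPs at these sizes solve in milliseconds.

## End-to-end interface

```{r}
library(qbiomass)
fx  <- demo_fixture()
md  <- setNames(list(fx$media), fx$media$id)
fit <- fit_biomass(fx$net, fx$experiments, md)   # de novo
summary(fit)
coef(fit)                                        # roles per metabolite
predict(fit, newdata = fx$experiments)           # FBA phenotype predictions
```
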