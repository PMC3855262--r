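# qbiomass

Qualitative biomass composition inference for constraint-based metabolic
models.

Genome-scale metabolic models predict growth with flux balance analysis
(FBA), and every FBA prediction hinges on the **biomass reaction** — the
list of metabolites the model must co-produce to grow. That list is usually
copied from a related organism and is often wrong. `qbiomass` infers or
repairs the biomass composition directly from qualitative gene-knockout
phenotypes (each mutant observed as growth `G` or no-growth `NG`), using
only the network stoichiometry, gene–protein–reaction (GPR) rules, and the
media definitions.

## How it works

1. **Blocked metabolites.** For the wild type and every mutant, a MILP
   partitions metabolites into net-producible and blocked on a
   sink-augmented network: maximize the number of metabolites whose sink
   carries flux, subject to `S v = 0`, bounds, and indicator linking
   `v_min * z_i <= x_i <= M * z_i`. A metabolite blocked in the mutant but
   not in the wild type is a *candidate* explanation for that mutant's
   phenotype.
2. **Include/exclude lists.** Each `NG` mutant contributes an *include*
   list (the biomass should contain at least one of its newly blocked
   metabolites); each `G` mutant contributes an *exclude* list (the biomass
   should contain none of them). Experiments with more than `filter_max`
   candidates are set aside as uninformative.
3. **Agreement integer program.** Binary `m_i` marks metabolite `i` as a
   biomass component; binaries `n_e`, `g_e` mark reconciled experiments:

   ```
   max  sum_e w_e * (n_e + g_e)
   s.t. n_e <= sum_{i in Include(e)} m_i        for NG experiments
        g_e <= 1 - m_i   for all i in Exclude(e) for G experiments
   ```

   A second pass fixes the optimal agreement and minimizes the component
   cost (cardinality, or preference-weighted). De novo selection starts
   from an empty composition; *modification* mode lexicographically
   maximizes agreement, then minimizes removals from a predefined
   composition, then minimizes additions. Ties among alternative optima are
   broken deterministically toward the lexicographically smallest set.
4. **Alternatives and precursors.** For each proposed component the solver
   enumerates exchangeable alternatives (swaps preserving the optimum) and
   classifies essential precursors, so a proposal is read as an equivalence
   class, not a unique answer.
5. **Dead-end repair.** A composition chosen from blocked-metabolite
   evidence can force by-products nothing consumes, pinning growth to zero.
   A per-experiment MILP demands a small biomass flux with sinks on all
   metabolites and minimizes the number of active sinks; the active sinks
   are folded into the biomass as consumed species and the augmentation
   iterates to a fixed point.
6. **Evaluation.** The final composition is scored by plain FBA against all
   experiments (threshold on biomass flux), reported per media condition.

All LPs/MILPs are formulated in-package and solved through the GLPK
command-line solver `glpsol` (see `SystemRequirements`).

## Worked example

```r
library(qbiomass)

fx  <- demo_fixture()                       # 10-metabolite teaching network
md  <- setNames(list(fx$media), fx$media$id)
fit <- fit_biomass(fx$net, fx$experiments, md)
print(fit)
#> Biomass composition fit (de_novo)
#> Biomass proposal (de_novo): 1 components, agreement 4
#>   components: C
#> FBA agreement: 100.0% over 4 experiments

summary(fit)
#> Biomass fit (de_novo): 1 components
#> IP agreement score: 4
#> Growth-prediction agreement: 100.0% overall (4 experiments)
#>    media_id observed n_experiments n_correct percent
#>  demo_media        G             3         3     100
#>  demo_media       NG             1         1     100
#> ...

# Repairing a predefined composition instead of building one from scratch:
mod <- fit_biomass(fx$net, fx$experiments, md, mode = "modify", mu = fx$mu)
mod$proposal
#> Biomass proposal (modification): 2 components, agreement 4
#>   components: C, H
#>   added: C | removed: F | unmodified: H
```

Models load from COBRA-style JSON or SBML (`read_model()`), phenotypes from
TSV (`read_phenotypes()`), media from JSON or TSV (`read_media()`). A
command-line interface covering each pipeline stage is installed at
`system.file("cli", "biomassfit", package = "qbiomass")`.

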