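Package: qbiomass
Title: Qualitative Biomass Composition Inference for Constraint-Based
    Metabolic Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers and repairs the biomass composition of genome-scale
    metabolic models from gene-knockout growth phenotypes. Mutant-specific
    sets of net-production-blocked metabolites are computed by mixed-integer
    programming, converted into include/exclude evidence lists, and a
    maximal-agreement integer program selects a minimal (or preference-
    weighted) biomass component set, either de novo or as a modification of a
    predefined composition. Companion analyses enumerate interchangeable
    alternative components, identify essential precursors under robust media,
    detect and repair dead-end by-products, and re-evaluate proposals by flux
    balance analysis. Includes a synthetic network and phenotype generator
    for validation, readers and writers for COBRA-style JSON and SBML/fbc
    models, and a command-line interface. Optimization is performed through
    the GLPK stand-alone solver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: GLPK stand-alone solver (glpsol) on the PATH
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
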