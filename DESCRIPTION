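Package: nemaspan
Title: Survival, Healthspan and Synergy Analysis for Combinatorial
    Longevity Interventions in C. elegans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for combinatorial longevity experiments in
    Caenorhabditis elegans: Kaplan-Meier survival estimation and log-rank
    comparisons of per-worm daily observations, motility-based three-state
    (mobile/impaired/frail) healthspan decomposition with restricted-mean
    state occupancy, classification of intervention combinations as
    synergistic, additive, intermediate or antagonistic over the subset
    lattice of measured strains, endpoint statistics (one-way ANOVA and
    Dunnett many-to-one comparisons) for pharyngeal pumping, stress and
    fecundity assays, and a Gompertz-hazard cohort simulator with
    FUdR-era censoring for fully reproducible in-silico cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    survival,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    multcomp
Config/testthat/edition: 3
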