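Package: eaimpact
Title: Aggregated Impact of Compounded Disturbances on Microbial Ecosystems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the impact of single and compounded (sequential)
    disturbances on ecosystem properties and functions in replicated
    microcosm experiments. Computes small-sample-corrected standardized
    mean differences (Hedges' g) of treated versus control replicates for
    every response variable, aggregates them into an Ecosystem Aggregated
    Impact (EAI) index with propagated variance, 95% confidence intervals
    and CI-overlap significance letters, and supports the surrounding
    analyses: per-timepoint ANOVA with Tukey HSD, rarefaction of OTU count
    tables, alpha diversity (observed species, Simpson's reciprocal,
    Faith's phylogenetic diversity), unweighted and weighted UniFrac
    distances, principal coordinates analysis, pairwise PERMANOVA, and
    sequential (Type-I) variance partitioning of the EAI against community
    composition predictors. Includes a synthetic microcosm-experiment
    generator so the whole pipeline is testable without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    vegan,
    picante,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    metafor,
    withr
Config/testthat/edition: 3
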