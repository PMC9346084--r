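Package: artemiadapt
Title: Survival, Dominance, Selection and Mitotype Analyses for
    Resurrection-Ecology Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for common-garden resurrection-ecology
    studies of thermal adaptation in Artemia franciscana. Fits tube-level
    binomial mixed models with observation-level overdispersion
    correction, pools control data into a multilevel random-effects
    meta-analysis of log odds ratios against the ancestral population,
    estimates the dominance of the evolved phenotypic change from
    crossed versus own-bred log-odds trajectories, simulates
    Wright-Fisher selective sweeps with arbitrary dominance, and tracks
    mitochondrial haplotype (mitotype) frequencies through time from
    pooled-sequencing base-fraction tables. Includes synthetic-data
    generators reproducing the statistical structure each stage assumes,
    so the whole pipeline is testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    mvtnorm,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    multcomp
Config/testthat/edition: 3
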