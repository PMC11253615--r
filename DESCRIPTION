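Package: guildscope
Title: Genome-Centric Guild Analysis of Microbiome Cohorts
Version: 0.1.0
Authors@R: person("Maintainer", "Guildscope", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A pipeline for genome-resolved, guild-based microbiome analysis:
    from a genome abundance matrix and clinical metadata to a two-guild
    microbiome signature. Implements compositional co-abundance inference
    (SparCC-style with permutation p-values), constrained-ordination (RDA)
    variable screening, PERMANOVA (single-factor, marginal, pairwise),
    guild detection via complete linkage on signed topological overlap,
    a per-sample guild index combining abundance with Gini-Simpson
    diversity, nonparametric group statistics with compact letter
    displays, random-forest classification with leave-one-out cross
    validation, ROC/PR evaluation, and guild-level functional contrasts.
    Includes a synthetic cohort generator with planted guild structure for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
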