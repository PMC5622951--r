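Package: probescore
Title: Probe-Level S-Score Differential Expression with One-Class SAM and
    Companion Assay Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Probe-level differential-expression analysis for PM-only
    transcriptome arrays via the S-score statistic: per-probe between-chip
    intensity changes standardized by an intensity-dependent error model and
    summed per transcript cluster, standard normal under the null. Includes
    One-Class Significance Analysis of Microarrays (sign-flip permutation
    false-discovery-rate estimation with a fudge-factor-stabilized statistic),
    gene-level two-factor (treatment by sex) linear models with optional
    empirical-Bayes variance moderation, local hypergeometric gene-set
    over-representation, behavioral endpoint statistics (discrimination index,
    loss of righting reflex, light-dark metrics, factorial ANOVA with
    Student-Newman-Keuls post hoc tests), delta-delta-Ct qPCR quantification
    against multiple reference genes, ELISA standard-curve back-calculation,
    and seeded synthetic-data generators with known ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    limma,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    car
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
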