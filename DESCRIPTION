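Package: metaVote
Title: Cross-Study Vote-Counting Consensus Analysis of Differential Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrative cross-study meta-analysis of case/control
    transcriptomics compendia by direction-aware vote counting. Provides
    per-comparison two-sample testing with Benjamini-Hochberg adjustment and
    an unadjusted-p fallback for statistically poor comparisons, molecule
    identifier harmonization, duplicate collapsing with sign-conflict
    removal, PCA-based stratification and robust outlier flagging of dataset
    comparisons, tiered frequency consensus scoring of consistently
    regulated molecules, cross-phenotype fold-change concordance
    classification, and gene-set over-representation with a pathway z-score
    and permutation null. Includes a synthetic compendium generator with
    planted, consistently regulated genes for calibration and recovery
    testing, and curated multiple-sclerosis consensus panels as worked
    examples.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
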