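Package: preanalytica
Title: Pre-Analytical Serum Quality Assessment for Targeted Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of pre-analytical sample-quality experiments for
    targeted serum metabolomics. Implements the Biocrates p150-style metabolite panel,
    kit-level quality control (pool CV and limit-of-detection filters), per-metabolite
    linear mixed-effects screening of pre-storage handling (time, temperature,
    interaction) and freeze-thaw effects with Bonferroni control, all-pairs log-ratio
    mixed models with the p-gain statistic, and a two-stage Random-Forest plus
    classification-tree procedure that derives an intrinsic good/bad sample-quality
    rule from lysophosphatidylcholine/phosphatidylcholine and amino-acid ratios. A
    synthetic-data generator reproduces the study design (19 donors, 13 aliquots each,
    pool and zero samples on 4 plates) so that every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    rpart,
    jsonlite
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
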