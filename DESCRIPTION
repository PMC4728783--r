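Package: semethyl
Title: Hypomethylated Region Segmentation and Super-Enhancer Methylation
    Analysis for Whole-Genome Bisulfite Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Segments CpG-resolution whole-genome bisulfite sequencing (WGBS)
    methylomes into hypomethylated regions (HMRs) with a two-state
    beta-binomial hidden Markov model, scores regions and filters them against
    a permutation null, detects unusually large HMRs by a tangent-slope-1
    ranking procedure, and quantifies DNA methylation of super-enhancers:
    scaled profiles over 50 percent flank extensions, HMR occupancy, delta
    occupancy differential calls, tissue specificity, and the association
    statistics linking methylation to histone signal and gene expression.
    Includes a local-likelihood smoother, a fully seeded synthetic WGBS data
    generator with ground truth, and a composable pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
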