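Package: panhybrid
Title: Biparental Call-Set Integration and Selection Scans for Hybrid Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates a single-reference genotype call set with a
    parental-panel (pan-genome) call set for a two-breed hybrid cohort under
    an explicit genotype-concordance rule, applies site-level quality control
    (missingness, minor allele frequency, exact Hardy-Weinberg test), and runs
    the downstream population-genomic analyses: genotype-class summaries,
    variant-density uniformity, principal component analysis, model-based
    admixture estimation, windowed Weir-Cockerham Fst, an XP-CLR-style
    composite-likelihood sweep scan, EigenGWAS with genomic control, and
    candidate-gene intersection with coding-consequence annotation. A
    forward-in-time pedigree simulator with a Balding-Nichols founder model
    and explicit reference-bias error models generates fully ground-truthed
    synthetic cohorts for testing every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
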