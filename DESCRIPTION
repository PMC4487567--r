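Package: fmdr
Title: Fast Multifactor Dimensionality Reduction for Gene-Gene
    Interaction Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects high-order gene-gene interactions (epistasis) in
    case-control single nucleotide polymorphism data with multifactor
    dimensionality reduction (MDR) and a fast greedy variant (FMDR) that
    prunes the combinatorial search order by order while retaining the
    best-scoring locus combinations per cross-validation fold.  Includes
    an imbalance-corrected high/low-risk cell labelling rule, balanced
    classification error scoring, ten-fold cross-validation with
    cross-validation consistency (CVC) model selection, odds-ratio and
    paired t-test reporting, and a pure-epistasis penetrance-model
    simulator for power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
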