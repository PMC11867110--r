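Package: gestaltphylo
Title: Bayesian Phylodynamics for GESTALT CRISPR Lineage-Tracing Barcodes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models GESTALT (genome editing of synthetic target arrays for
    lineage tracing) barcode alignments as the outcome of a clock-scaled
    continuous-time Markov chain of dependent, irreversible target-site
    editing. Provides the target-tract editing model, a Felsenstein pruning
    likelihood over ancestral indel states with masking by inter-target
    deletions, a forward simulator of birth-death trees and barcode
    alignments, birth-death-sampling and exponential-growth coalescent tree
    priors, a Metropolis-Hastings sampler over editing, tree and
    phylodynamic parameters, and a simulation-based calibration harness with
    tree-imbalance diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    jsonlite,
    Matrix,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
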