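Package: msaensemble
Title: Ensemble Multiple Sequence Alignment and Confidence Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds ensembles of high-accuracy multiple sequence alignments by
    posterior decoding of a double-affine pair hidden Markov model, iterative
    consistency transformation and maximum expected accuracy progressive
    alignment, with replicate diversity introduced by random perturbation of
    HMM probabilities and permutation of the guide tree. Provides ensemble
    confidence metrics for alignments (column confidence CC, alignment
    confidence AC, mean AC) and for phylogenetic trees (edge confidence,
    topology confidence of designated subgroups via condensed trees, and
    ensemble monophyly from best-fit subtrees), together with outgroup
    rooting, a deterministic sequence-family simulator for testing, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    phytools,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite
Config/testthat/edition: 3
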