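Package: cubdecay
Title: Neutral Decay of Codon Adaptation under Context-Dependent Mutation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to ask whether the codon adaptation of a gene is maintained
    by selection or is merely an ancestral bias decaying under mutation
    pressure. Estimates context-dependent nucleotide mutation models from
    aligned noncoding triplets (two ingroup sequences polarized by an
    outgroup), converts substitution count matrices into row-stochastic
    probability matrices with stationary base compositions, computes the
    Codon Adaptation Index (CAI) from reference-gene fitness tables, and
    simulates the neutral decay of CAI from reconstructed ancestral coding
    sequences under synonymous-only or dN/dS-gated mutation acceptance.
    Kimura two-parameter distances position extant genes on the simulated
    trajectories for comparison against the neutral expectation. Includes a
    synthetic-data generator so every stage can be exercised without external
    sequence databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    Biostrings,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
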