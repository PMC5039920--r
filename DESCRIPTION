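Package: chipstate
Title: Joint Discretization of Replicated ChIP-seq Profiles with
    Built-In Quality Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Converts one or more replicated ChIP-seq read profiles and
    their negative controls into a single three-state (low/medium/high)
    window track using a hidden Markov model with zero-inflated negative
    multinomial emissions. The zero-inflation and shape parameters are
    fitted from the control profiles by a Newton-type maximum-likelihood
    solver, the state-dependent emission parameters and transition matrix
    by Baum-Welch, and the final segmentation by the Viterbi algorithm.
    A support vector machine over five discretization-derived summary
    statistics issues an all-or-none quality-control verdict for the
    whole profile. Includes a generative simulator for the same model,
    utilities to read and bin BED/SAM/BAM alignments into fixed-step
    windows, and discretizer-comparison tools (Pareto-front placement,
    motif-reference precision/recall, variance explained).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    GenomicAlignments,
    rtracklayer,
    Rsamtools,
    e1071
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
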