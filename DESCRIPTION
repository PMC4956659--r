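Package: knotdesign
Title: Defect-Weighted Sequence Design for Pseudoknotted RNA Secondary
    Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Inverse folding of RNA secondary structures that contain
    pseudoknots. Targets are "two-page" structures whose base pairs split
    into two mutually non-crossing sets (round and square bracket layers of
    the extended dot-bracket notation). Sequences are optimized by an
    adaptive defect-weighted stochastic local search that minimizes the
    normalized ensemble defect, with three mutation operators guided by
    equilibrium base-pair probability matrices and an adaptive
    multi-position mutation schedule. Equilibrium quantities (partition
    function, augmented pair-probability matrix and its nested and
    non-nested components, ensemble defect, probability defect, MFE defect,
    Boltzmann frequency) are computed over the full two-page ensemble by an
    exact compiled enumerator under a configurable additive pair-energy
    model, with a dynamic-programming fast path for pseudoknot-free
    ensembles and an optional adapter for an external folding engine.
    Includes design templates that lock conserved motif nucleotides, a
    synthetic two-page target generator, trial summaries with sign-test
    comparisons, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
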