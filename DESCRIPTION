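Package: deepalign
Title: Deep Superposition-Space Search for Pairwise Protein Structure
    Alignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pairwise protein structure alignment from alpha-carbon traces.
    Implements three classical heuristic aligners (STRUCTAL-style iterative
    dynamic programming with linear gaps, TM-align-style affine-gap scoring
    on a given superposition, and LOCK2-style mutual-nearest-neighbour
    refinement), a deep search of rigid superposition space that maximizes
    the number of residue pairs fit under a distance cutoff, exhaustive
    small-instance oracles for validating the search and the dynamic
    programming cores, a battery of alignment quality metrics (NumPairs,
    Similarity Index, PSI, shift-tolerant agreement with reference
    alignments), and a generator of protein-like synthetic chains and decoy
    pairs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
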