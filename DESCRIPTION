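Package: permalign
Title: Read Alignment with Random Permutations of Sorted Substring Indexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Short-read alignment by randomized nearest-neighbour search in
    Hamming space. The reference genome is indexed as a collection of
    lexicographically sorted arrays of randomly permuted M-mers; reads are
    located by binary search, candidate loci are harvested from sorted-array
    neighbourhoods over several independent permutations, coarsely filtered
    by hit counts and ranked by Hamming distance. Includes the closed-form
    success-probability calculus used to plan the number of permutations,
    paired-end alignment with indel-tolerant mate rescue by banded edit
    distance, a wgsim-style read simulator with ground-truth records for
    evaluation, and SAM output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    Rsamtools,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
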