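Package: genosketch
Title: Sketching Algorithms for Fast Genome Similarity Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compact sketch data structures for alignment-free comparison of
    nucleotide sequences: bottom-s (KMV) MinHash with Jaccard and Mash-distance
    estimation, OrderMinHash as an edit-distance-sensitive similarity,
    Kssd-style deterministic k-mer substring space sampling, and HyperLogLog
    cardinality sketches. All sketch families support streaming construction
    and merging; an inverted-index engine accelerates all-vs-all comparison of
    many genomes while remaining exactly equivalent to the naive pairwise loop.
    Includes a synthetic-genome fixture generator and a command-line interface
    for sketching, pairwise distance tables, and sketch inspection.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
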