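Package: sweepmap
Title: Alignment-Free Local Alignment Boundary Estimation with
    Plane-Sweep Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Computes approximate local alignment boundaries and identity
    estimates between long DNA sequences without base-level alignment.
    Given a minimum alignment length and a maximum per-base error rate,
    the query is split into half-length fragments, each fragment is
    mapped end-to-end against a minimizer index of the reference using
    winnowed-MinHash Jaccard estimation under a Poisson error model, and
    consecutive fragment mappings are merged into scored segments.
    Probabilistic sensitivity guarantees follow from a binomial model of
    shared sketch hashes.  Redundant mappings are removed by an optimal
    plane-sweep interval filter with 'map' and 'one-to-one' modes.
    Includes deterministic simulators of mutated and duplicated genomes
    for validation, a tab/PAF writer and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
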