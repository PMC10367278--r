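Package: lsbucket
Title: Locality-Sensitive Bucketing Functions for the Edit Distance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Deterministic locality-sensitive bucketing (LSB) functions for
    fixed-length sequences under the Levenshtein (edit) distance. An LSB
    function maps a length-n sequence to a set of buckets so that any two
    sequences within edit distance d1 share at least one bucket while any two
    at distance d2 or more share none. The package provides the optimal
    (1,2)-sensitive construction over the full sequence space together with an
    O(n) per-sequence bucket-id formula, the recursive partition of the
    sequence space into minimum (1,1)-guaranteed subsets with an O(n)
    membership query, neighborhood-based bucketing schemes with proved
    (d1,d2) guarantees, an exhaustive sensitivity verifier, a collision
    frequency simulator for random sequence pairs at exact edit distances,
    and a command-line tool that buckets length-n windows of FASTA records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    optparse,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
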