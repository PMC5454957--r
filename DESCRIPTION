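Package: rwrprio
Title: Disease-Gene Prioritization by Random Walk with Restart on
    Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Ranks candidate disease genes on a weighted protein-protein
    interaction network by random walk with restart (RWR) from a set of
    validated seed genes, filters the ranked genes by a permutation-test
    p-value and by two association criteria (maximum interaction score to
    any seed, maximum functional similarity of hypergeometric enrichment
    profiles), and evaluates the resulting pipeline by k-fold
    cross-validation against a guilt-by-association nearest-neighbor
    baseline. Includes parsers for STRING-style weighted edge lists, seed
    lists and GMT annotation files, and a synthetic-data generator that
    plants a disease module in a random background network for desk-scale
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
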