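Package: mirulenet
Title: Discriminatory Interval Rules and miRNA-mRNA Regulatory Modules
    from Paired Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers 100%-frequency discriminatory interval rules from
    two-class miRNA expression profiles via gain-ratio ranking and a
    committee of decision trees, mines matching mRNA rules with a greedy
    compactness search over predicted-target expression, links the two
    rule sets through a miRNA-to-target map into bipartite regulatory
    modules with Pearson-signed edges (inverse and positive regulation),
    and assesses seed-region complementarity in UTR/CDS sequences with a
    first-order Markov background model. Includes a synthetic-data
    generator with planted, recoverable structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    pROC,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
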