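Package: hubnet
Title: Multi-Study Rank-Product Meta-Analysis and Network Hub-Gene Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for nominating candidate disease genes from multiple
    gene-expression studies and a protein-interaction background. Implements
    rank-product meta-analysis of per-study fold changes with permutation-based
    false-prediction-proportion (pfp) estimates, mapping of differentially
    expressed genes onto an integrated interaction network, a Steiner
    minimal-tree subnetwork reduction, cohesiveness-based detection of dense
    (possibly overlapping) network modules, a distance/degree hub-gene
    criterion, a per-dataset expression-concordance ("validated rate")
    statistic, hypergeometric gene-set over-representation, and
    immunoreactivity-score summaries for immunohistochemistry cohorts. A
    synthetic-data generator produces multi-study expression matrices with
    planted differential genes and batch structure, background networks with
    planted dense modules and hubs, and IHC score tables, so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
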