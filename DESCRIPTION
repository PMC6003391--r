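Package: taxaudit
Title: Auditing Taxonomy Annotations and Guide Trees in 16S rRNA Reference
    Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for auditing taxonomy annotations and guide trees
    distributed with 16S rRNA reference databases. Parses lineage
    annotations in the RDP, Greengenes and SILVA dialects, detects
    conflicting annotations of identical sequences between two databases
    and derives a lower bound on the sum of their annotation error rates,
    analyses the purity (tree-level monophyly) of taxa on rooted guide
    trees via lowest-common-ancestor subtrees, computes the Taxonomy
    Concurrence Score between two trees over a shared annotated leaf set,
    evaluates taxonomy classifiers with blinded-test metrics
    (over/under/mis-classification rates), scans databases for
    high-identity outlier pairs at each lowest common rank, and simulates
    annotated database pairs and perturbed trees with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phytools,
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
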