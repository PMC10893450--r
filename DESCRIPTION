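Package: wgdinfer
Title: Whole-Genome Duplication Inference from Ks Distributions and Gene-Tree
    Reconciliation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect and date whole-genome duplication (WGD) events
    from coding-sequence collections. Implements Nei-Gojobori (NG86) Ka/Ks
    estimation on codon alignments, node-weighted Ks age distributions for
    paralog and ortholog pairs, Gaussian mixture modelling with BIC component
    selection to locate WGD signature peaks, LCA reconciliation of gene trees
    against a species tree with (AB)(AB) duplicate-retention typing and
    dual-criterion WGD calling, Ks-to-age dating, cross-lineage synonymous-rate
    correction, positive-selection screening, hypergeometric functional
    enrichment and gene-fraction statistics. Ships a codon-level forward
    simulator that plants WGD episodes on a species tree with known ground
    truth, so every stage of the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    mclust,
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
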