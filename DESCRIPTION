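Package: orthoarray
Title: Cross-Species Microarray Analysis via Orthologous Probe Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds "virtual array" library files for cross-species analysis of
    short-oligonucleotide microarrays. Perfect-match 25-mer probes are matched
    against a target-species cDNA database with an exact seed-and-extend
    matcher, classified into orthology tiers (exact, terminal-mismatch, tandem,
    rescue), filtered for gene specificity, and assembled into probe sets
    mapped one-to-one to target genes. Expression estimates are recomputed
    from CEL intensities with a from-scratch RMA (normexp-style background
    correction, quantile normalization, median polish), transcripts are ranked
    by predictive error of single-input neural network classifiers under
    random-sample cross-validation, marker interactions are scored by network
    input gradients, and differential genes are tested for gene-set enrichment
    with hypergeometric p-values and Benjamini-Hochberg FDR control. A
    deterministic synthetic-data generator with planted ground truth supports
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    methods,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    limma,
    knitr,
    rmarkdown
Config/testthat/edition: 3
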