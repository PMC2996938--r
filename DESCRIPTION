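Package: mescan
Title: Mobile Element Scanning by Targeted Paired-End Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies and genotypes (presence/absence) mobile element
    insertions of a target retrotransposon subfamily from indexed, pooled,
    paired 2x36-bp junction/flank sequencing libraries. Implements sample-index
    demultiplexing with single-mismatch correction, read quality screening,
    dual intact/trimmed junction mapping with pair-level filters, junction
    endpoint locus identification with neighbourhood merging and motif
    validation, primer binding site scanning and locus annotation, selection
    of putatively fixed reference loci, and the evaluation statistics used to
    assess such assays (index proportion recovery, false negative rate,
    adjusted sensitivity, specificity, replication failure rate, coverage
    overdispersion). A wet-lab-emulating simulator generates references with
    planted target and decoy elements, segmental duplications, cohorts with
    configurable allele frequencies, and overdispersed indexed libraries with
    per-pair truth tables, so the whole pipeline can be validated hermetically.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rsamtools,
    Rcpp,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
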