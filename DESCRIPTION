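Package: circfleval
Title: Long-Read Validation of Assembled Full-Length circRNA Sequences
Version: 0.1.0
Authors@R:
    person("circfleval", "developers", email = "circfleval@example.org",
           role = c("aut", "cre"))
Description: Tools to evaluate the correctness and completeness of circRNA
    full-length sequences assembled from short reads, using long reads of the
    same sample. Implements rotation-based read-alignment validation of
    back-splice junction (BSJ) internalized references, matching against
    reference full-length isoform sets, k-of-n ensemble verdicts,
    cross-strategy precision/sensitivity/F1 confusion counts, precision
    stratified by back-splice read support, and a screening protocol that
    retains only exonic candidates whose sequence equals the complete
    annotated exon chain between their back-splice sites. A deterministic
    synthetic-data module generates a toy genome, gene annotation, true
    circRNA isoforms, rolling-circle long reads with a configurable error
    model, and corrupted candidate sets with planted correctness so that
    every pipeline stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    jsonlite,
    methods,
    optparse,
    Rcpp,
    Rsamtools,
    rtracklayer,
    stats,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
SystemRequirements: C++17
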