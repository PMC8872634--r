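Package: fflatt
Title: Feed-Forward-Loop Enriched Gene Regulatory Network Generation and
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Grows directed gene regulatory network graphs enriched in
    feed-forward loop (FFL) motifs by motif-based preferential attachment,
    with controlled size, sparsity and FFL node participation. Provides a
    five-class census of connected three-node motifs with role-resolved FFL
    participation, degree-preserving edge-swap null models and motif
    enrichment Z-scores, baseline generators (uniform random digraph,
    random DAG, directed scale-free growth), and a transcription-allocation
    stability analysis that scores networks by the leading real part of the
    Jacobian spectrum at the expression steady state.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
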