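Package: sonata
Title: Diagnosing Ambiguous Mappings in Diagonal Single-Cell Multi-Omics
    Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Diagnostic add-on for diagonal (anchor-free) integration of
    multimodal single-cell data. Detects cell-cell manifold ambiguity within
    a modality by repeatedly aligning the modality to noise-perturbed
    variational copies of itself with entropic Gromov-Wasserstein optimal
    transport, calls statistically significant ambiguous cell pairs against
    an antitonic spline null model of correspondence probability versus
    geodesic distance, aggregates ambiguous cells into substitutable groups
    by cannot-link constrained clustering, and emits alternative
    cross-modality integration solutions obtained by soft permutation of the
    ambiguous groups. Includes a simulator for branched and decay-path
    manifold benchmarks and the FOSCTTM and label-transfer-accuracy
    evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
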