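Package: polyclone
Title: Clonality Inference and Collision Null Models for Confetti
    Lineage-Traced Intestinal Tumours
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for inferring the clonal composition of mouse intestinal
    tumours from multicolour (Confetti) lineage tracing and targeted amplicon
    sequencing. Simulates stochastic Confetti crypt labelling and quantifies
    contiguous same-colour patches; evaluates random tumour-collision null
    models analytically (Poisson approximation to inter-adenoma spacings),
    by placement simulation, and by growth-based Monte-Carlo simulation with
    spatial density diagnostics; filters amplicon variant calls and classifies
    tumours as monoclonal or polyclonal with major/minor clone assignment and
    purity estimates from variant allele fractions; computes stratified
    non-parametric bootstrap confidence intervals for per-domain Apc
    mutation-probability differences; fits mixed-effects exponential growth
    contrasts; and builds pseudo-bulk count mixtures of paired clones. A
    synthetic cohort generator with known ground truth makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    Matrix,
    nlme,
    stats,
    tools,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
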