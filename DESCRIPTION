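Package: dyde
Title: Dynamical Differential Expression Analysis of Gene Regulatory Networks
Version: 0.1.0
Authors@R: person("DyDE", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects circadian-regulated transcripts in short expression
    time courses by fitting pseudo-sinusoidal waveforms and classifying
    spectral features with logistic regression, then localizes the entry
    point of a chemical perturbation in a gene regulatory network by
    fitting first-order linear time-invariant models to all directed gene
    pairs in two conditions and comparing link dynamics with the nu-gap
    metric and connectivity-loss analysis. Includes a synthetic two-condition
    data generator with known link kinetics, AUROC/AUPR benchmarking of
    link recovery, and a command-line pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
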