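Package: crossnorm
Title: Scale-Based Normalization and Exact Tests for Cross-Species RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential-expression analysis of RNA-seq read counts between two
    different species, where orthologous genes differ in length and libraries
    differ in sequencing depth. Implements a gene-length- and depth-adjusted
    conditional binomial exact test for orthologous gene pairs, the SCBN
    (scale-based normalization) estimator of the cross-species scaling factor
    that minimizes the deviation between empirical and nominal type-I error over
    a set of conserved orthologous genes, a median-ratio baseline normalizer,
    positive-false-discovery-rate estimation, a Poisson count simulator with
    known ground truth, and evaluation metrics (false-discovery number,
    precision, sensitivity, F-score, MA values) with replicated study runners.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
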