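Package: gflcnv
Title: Joint Copy-Number Segmentation of Multiple Signals with a Generalized Fused Lasso
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Joint segmentation of multiple DNA copy-number signal sequences
    (SNP-array Log R Ratio and mirrored B Allele Frequency) with a generalized
    fused lasso combining a sparsity penalty, a per-sequence total-variation
    penalty and a group penalty on the column vector of jumps. The smoothed
    objective is minimized by a majorization-minimization algorithm whose inner
    step reduces to one symmetric positive-definite tridiagonal linear solve per
    sequence, giving O(MN) cost per iteration and support for sequences observed
    on only partially overlapping probe grids. Includes default penalty tuning
    rules driven by a robust noise estimate, two-stage jump thresholding (ruler
    heuristic and a modified BIC), a five-state likelihood-ratio copy-number
    caller on BAF and LRR, and synthetic-data generators (normal cohorts with
    inserted CNVs, tumor-normal in-silico dilutions, pedigree-style shared CNVs)
    with per-SNP sensitivity/FDR scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    Matrix,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
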