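Package: cohortscreen
Title: Donor-Variable Drug Response Analysis for Cell Painting Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-donor, multi-drug Cell Painting
    screens of induced pluripotent stem cell lines. Provides robust Z-score
    normalization against per-plate DMSO controls, coefficient-of-variation
    and Spearman-redundancy feature filters, the induction drug-response
    statistic, Euclidean distance-to-control tables, cross-run
    reproducibility via per-feature Earth Mover Distances, responder
    stratification, and responder-stratified differential proteomics with
    permutation-based FDR. Includes a plate-structured synthetic screen and
    DIA-style proteome generator with known ground truth so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    cluster,
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    uwot,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
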