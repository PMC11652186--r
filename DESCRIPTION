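Package: ocrchart
Title: Control-Chart Classification of Chromatin Accessibility from
    cfDNA Fragmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Classifies genomic regions into open, partially open and
    closed chromatin states from cell-free DNA (cfDNA) fragmentation
    signals using multivariate statistical process control. Provides a
    seeded synthetic cfDNA fragment generator with nucleosome
    periodicity, featurization of fragments into windowed protection
    score (WPS), coverage and fragment-end tracks, a robust Hotelling
    T-squared control chart built on an in-package minimum regularized
    covariance determinant (MRCD) estimator with Monte-Carlo
    moment-matched F control limits and genomic run rules for filtering
    noisy training labels, a sensitized T-squared chart fusing MEWMA
    chart probabilities with a noise-tolerant classifier for three-class
    calling, and a confident-learning plus co-teaching stage for final
    label refinement.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    pROC,
    purrr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
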