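Package: wristmss
Title: Smartwatch Motion Segment Size Analysis for Upper-Extremity Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs wrist orientation from single-smartwatch inertial
    recordings (strapdown gyroscope integration in a button-press calibration
    frame), segments acceleration and Euler-angle signals at direction
    reversals, and computes the average motion segment size (MSS), a
    threshold-filtered total-variation measure of movement smoothness and
    magnitude used to track upper-extremity function in stroke rehabilitation.
    Includes clinical-score handling (ARAT, FMUE, MBI), Spearman correlation
    and pre/post change analyses, and a synthetic cohort generator that
    emulates impairment-graded task recordings so the full pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
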