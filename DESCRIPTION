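Package: aifnet
Title: Neural Correction of Arterial Input Function Saturation for
    Quantitative Stress Perfusion Cardiac MR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative first-pass stress perfusion cardiac
    magnetic resonance. Implements a 1D U-Net that predicts the unsaturated
    arterial input function (AIF) from the saturated AIF of a standard
    single-sequence acquisition, trained on paired dual-sequence curves;
    a saturation-recovery signal model with relative-enhancement
    concentration conversion; Fermi-function-constrained deconvolution for
    myocardial blood flow (MBF) estimation with AHA 16-segment and coronary
    territory diagnostic classification; a physics-based synthetic
    dual-sequence cohort generator for training and validation without
    patient data; and agreement statistics (NMSE, curve shape metrics,
    Bland-Altman, rank-sum comparisons, diagnostic agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
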