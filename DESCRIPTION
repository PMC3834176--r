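Package: isobolr
Title: Type II Isobolographic Analysis of Fixed-Ratio Drug Mixtures
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for type II isobolographic analysis of two-drug
    mixtures in which one drug is fully effective and the other is
    ineffective alone. Fits maximum-likelihood log-probit curves to
    quantal dose-response data and derives the median effective dose
    (ED50) with 95% confidence limits and SEM, predicts the theoretical
    additive ED50 and SEM for fixed-ratio mass mixtures, classifies
    interactions as supra-additive, additive or sub-additive with
    Welch's t-test on summary statistics, renders tabular reports and
    type II isobolograms, and simulates quantal experiments with a
    controllable interaction index for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
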