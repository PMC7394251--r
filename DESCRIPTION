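Package: assaybias
Title: Analytical Bias Assessment for Paired Method-Comparison Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the analytical bias of a test method
    (typically an automated immunoassay) against a reference method
    (typically LC-MS/MS) from paired patient measurements. Implements
    per-sample absolute and relative bias with Bland-Altman summaries,
    simple and weighted Deming (errors-in-variables) regression with
    jack-knife standard errors and confidence intervals, proportional-bias
    curves along the concentration axis with jack-knife confidence bands,
    regression-suitability diagnostics (Pearson correlation,
    Anderson-Darling normality of standardized residuals, CUSUM linearity),
    and CLSI EP09-style comparability verdicts. Includes a synthetic
    paired-measurement generator with heteroscedastic proportional noise,
    calibration bias and additive cross-reactivity interference, plus six
    presets emulating common serum steroid immunoassays.
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
    nortest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
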