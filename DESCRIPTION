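Package: waldgenkin
Title: Wald-Genkin Sequential Prognostic Tables for Two-Group Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds and applies Wald-Genkin prognostic tables for two-group
    screening from binary criteria. Computes anthropometric and functional
    indices (Erisman index, proper vital lung capacity, biceps index),
    binarizes subjects against configurable age and height norms, estimates
    deciban predictive coefficients (10*log10 likelihood ratios) and Kullback
    informativeness from two-cohort exceedance counts, assembles the filtered
    prognostic table, and classifies individuals by sequential summation of
    coefficients to a symmetric deciban threshold. Includes an exhaustive
    inversion oracle recovering integer exceedance counts from printed
    coefficient pairs, a two-tier synthetic cohort generator, and Monte-Carlo
    validation of threshold error semantics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
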