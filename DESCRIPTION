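Package: wmhseg
Title: 3D White-Matter-Hyperintensity Segmentation, Volumetry and
    Cognitive Correlation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic 3D segmentation of white-matter hyperintensities (WMH)
    on FLAIR-like volumes with a residual encoder using multi-layer
    cross-connected shortcuts and a decoder with spatial-attention-weighted
    deep supervision, trained with a soft-Dice plus cross-entropy loss.
    Includes lesion volumetry in mm3 with a signed over/under-segmentation
    ratio, cohort block summaries, covariate-adjusted (partial) correlation of
    WMH volume with neuropsychological scores, one-way ANOVA with Fisher LSD
    pairwise comparisons, and a synthetic FLAIR phantom and cohort generator
    so the full pipeline runs without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
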