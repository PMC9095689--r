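Package: soleusshape
Title: Statistical Shape Modelling of Soleus Muscle Morphology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds point-distribution shape models of elongated skeletal
    muscles from triangulated surface meshes. Establishes dense correspondence
    by radial-basis-function non-rigid registration with iterative mean-shape
    refitting, aligns specimens by centre of mass and principal axes of
    inertia, and decomposes the corresponded cohort by principal component
    analysis into morphological (size-retaining) and appearance
    (size-normalized) models. Includes leave-one-out generality validation,
    mean-shape difference maps with Hausdorff summaries, a per-component
    two-group statistical test battery (Shapiro-Wilk, Levene, pooled t-test
    with Holm-Bonferroni correction, Kruskal-Wallis fallback), and a synthetic
    generator of soleus-like muscle mesh cohorts with known ground-truth
    deformation modes for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    rlang,
    tibble,
    dplyr,
    readr,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
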