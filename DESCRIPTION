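Package: icvnorm
Title: Intracranial-Volume Normalization and Robust Laplace Aging Trajectories for Brain ROI Volumetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for studying how intracranial-volume
    (ICV) normalization removes sex and race differences in brain region-of-
    interest (ROI) volumes. Provides a synthetic cohort generator calibrated to
    printed demographic and ICV group statistics, quality-control aggregation of
    multi-scan multi-visit records, four ICV-correction schemes (division,
    residual, covariate, matching) plus a ventricle log-transform, robust
    location-scale aging-trajectory fitting under a Laplace likelihood with
    B-spline location and scale curves maximized by gradient ascent, and
    pooled-scale effect sizes between demographic groups across age.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    splines,
    stats,
    utils,
    jsonlite,
    yaml,
    readr,
    generics,
    digest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
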