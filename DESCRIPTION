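Package: yolkflow
Title: Quantification of Yolk-Cell Cortical Dynamics from Time-Lapse Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An image-quantification toolkit for cortical dynamics of the
    zebrafish yolk cell during epiboly. Estimates actomyosin flow fields from
    punctate actin time-lapse movies by windowed cross-correlation (particle
    image velocimetry) with signal-to-noise and speed-cap vector filtering and
    directional (rose/quadrant) summaries; fits fluorescence recovery after
    photobleaching (FRAP) half-times; measures laser-ablation recoil
    velocities from gap-opening kinetics; quantifies fluorescence
    accumulation slopes, size-filtered endocytic puncta counts, microtubule
    plus-end comet speeds, and whole-embryo morphometry (circularity, epiboly
    progression). Includes a synthetic time-lapse generator with exported
    ground truth so every stage is validated end to end, plus the group-level
    hypothesis tests used on per-embryo summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
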