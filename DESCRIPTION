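Package: gliatile
Title: Automated Quantification of Glial Tiling in Confocal Z-Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An automated image-analysis pipeline for quantifying glial-glial
    tiling in the Drosophila larval central nervous system from three-channel
    confocal Z-stacks. Provides per-channel unsharp-mask denoising,
    quality-aware global thresholding with a per-channel algorithm-selection
    decision tree (Otsu, Triangle, Li, Yen), binary-morphology segmentation of
    the cortex region, a perimeter-based automated morphology index (AMI) for
    cortex glia, an overlap-based automated infiltration score (AIS) for
    astrocyte processes with shape-based cell-body exclusion, and the
    downstream spatial statistics: per-animal global scores, dorsal-ventral
    sliding-window profiles, Spearman correlation, Kruskal-Wallis with Dunn
    post hoc comparisons, manual-versus-automated validation regression, and
    ICC(3,k) rater agreement. A seeded synthetic-fixture generator with known
    ground truth supports testing and demonstration without real microscopy
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
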