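Package: segrel
Title: Inter- and Intra-Operator Reliability of 3-D Lesion Segmentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying agreement between repeated manual
    segmentations of 3-D medical images, built around the volumetric
    Sorensen-Dice coefficient and the non-overlapping segmentation volume.
    Reads binary lesion masks (NIfTI) and a cohort manifest, assembles the
    four standard comparison sets of a two-operator, two-session reliability
    design (inter-operator per session, intra-operator per operator),
    stratifies agreement by lesion type and lesion size, and compares groups
    with the Kruskal-Wallis rank test. Includes a calibrated synthetic-cohort
    generator that produces paired operator segmentations with controllable
    Dice agreement, so the full analysis pipeline can be exercised and tested
    without access to clinical CT data.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
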