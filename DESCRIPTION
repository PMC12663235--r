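Package: maskrec
Title: Reconciling Candidate Cell Segmentation Masks by Integer Programming
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fuses two candidate binary segmentation masks of a stained tissue
    image (typically a detector-derived mask and a segmenter-derived mask) by
    relabeling only the pixels where the two masks disagree. Patch-local
    foreground and background Gaussian mixture models over RGB intensities
    supply per-pixel foreground probabilities; a binary labeling problem with a
    Potts-type color-similarity smoothness term is then solved exactly by
    min-cut/max-flow, by a 0-1 linear program, or by brute-force enumeration.
    Includes mask-averaging baselines, conversion of semantic masks to instance
    masks guided by detector boxes, instance segmentation metrics (Dice, IoU,
    AJI, PQ, Boundary-F1), and a seeded generator of histology-like synthetic
    scenes for testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    generics,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    igraph,
    jsonlite,
    png,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
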