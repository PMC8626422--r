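Package: xlinktools
Title: Photocrosslinking Interactome Screens, Mitotic Foci Quantification,
    and iCLIP rRNA Crosslink Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable implementations of three desk analyses for studies of
    kinase-substrate capture by genetically encoded photocrosslinkers: (1)
    dual-crosslinker quantitative proteomics screen statistics with Welch
    difference volcano coordinates and quadrant hit classification; (2)
    fluorescence foci ("M-body") quantification with control-calibrated
    percentile thresholding, size-gated connected-component detection and
    per-cell counting; (3) iCLIP crosslink-profile analysis on ribosomal RNA
    with UMI collapsing, per-sample depth normalization, Gaussian metaprofile
    smoothing and expansion-segment window quantification. Each stage is
    driven either by user tables/images or by bundled synthetic-data
    generators with known ground truth, enabling parameter-recovery
    simulation of the full pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
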