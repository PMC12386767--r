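Package: yapscreen
Title: Dual-Modality RNAi Kinome Screen Analysis for YAP/TAZ Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for paired high-content RNAi screens of the
    Hippo/YAP-TAZ pathway: quantification of YAP/TAZ nuclear/cytoplasmic
    distribution from two-channel (DAPI/FITC) fluorescence images,
    plate-based Z-score hit calling for the localization modality,
    beta-galactosidase-normalized TEAD-luciferase reporter fold-change hit
    calling, multi-level integration of hits across modalities and cell
    lines, and delta-delta-Ct qPCR follow-up quantification. Includes a
    synthetic-data generator (plate layouts, well-level measurements and
    rendered microscopy image pairs with ground truth) so the full pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
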