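Package: filoscaffold
Title: Quantification of Endothelial Filopodia Dynamics and Nuclear
    Engagement in 3D Microscaffolds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify endothelial cell behaviour on hexagonal
    3D microscaffolds from fluorescence microscopy: 3D nucleus
    segmentation with in-plane orientation and vertical engagement
    (bottom-z) statistics, per-frame filopodia detection on timelapse
    movies with a pluggable ridge-enhancement detector, frame-to-frame
    track linking by linear assignment on an intersection-over-union
    cost, censoring-aware lifetime and per-extremity speed estimation,
    Savitzky-Golay kinetic-curve smoothing and paired pre/post-treatment
    statistics.  A calibrated synthetic-microscopy generator (scaffold
    lattices, oriented nuclei stacks, dynamic filopodia movies with full
    ground truth) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    signal,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
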