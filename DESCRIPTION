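Package: prothallus
Title: Cell Division Dynamics in Fern Gametophyte Apical Meristems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative image-analysis pipeline for cell division dynamics in
    fern gametophyte apical meristems, built around propidium-iodide style
    membrane-stain images of flat, one-cell-thick prothalli. Provides
    marker-controlled watershed segmentation with per-cell area quantification
    and area colour maps, time-lapse lineage tracking with division detection,
    anticlinal/periclinal division-orientation calls against the tissue margin,
    three-celled packet detection with Type I-IV division classification,
    marginal/submarginal layer statistics, and size-versus-division and growth
    rate comparisons. A cell-based growth simulator reproduces the division
    grammar of the apical initial and of the multicellular apical meristem and
    renders ground-truthed synthetic stain images, so every pipeline stage can
    be validated without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
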