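Package: perilymph
Title: Quantification of Peri-Lymphatic Chemokine Gradients, Dendritic Cell
    Localization and Circadian Rhythmicity in Skin Whole Mounts
Version: 0.1.0
Authors@R:
    person("Perilymph", "Maintainers", email = "maintainers@perilymph.dev",
           role = c("aut", "cre"))
Description: Tools for quantifying dendritic-cell migration into skin
    lymphatic vessels from whole-mount fluorescence microscopy: exact
    Euclidean distance transforms of binary vessel masks in metric units,
    distance-binned chemokine (CCL21) intensity profiles with replicate
    averaging and day/night normalization, distance-zone segmentation of the
    interstitium, inside/outside-vessel cell counting normalized to vessel
    volume, Golgi-resolved intracellular intensity ratios, fixed-period
    cosinor rhythmometry with zero-amplitude testing, immunofluorescence
    screen normalization, bioluminescence detrending by centered moving
    average, and cell-track chemotaxis metrics (velocity, directionality,
    accumulated and Euclidean distance). A synthetic-scene simulator
    generates every input with known ground truth so the full pipeline is
    testable without microscope data. A command-line interface ties the
    stages into reproducible, seeded runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
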