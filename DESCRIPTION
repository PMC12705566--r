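Package: eemstress
Title: Excitation-Emission Matrix Fluorescence Analysis for Plant Stress
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing excitation-emission matrix (EEM)
    fluorescence spectra of plant root exudates under pollutant stress.
    Provides scatter (Rayleigh/Raman) removal with interpolation and
    smoothing, characteristic fluorescence peak quantification, trilinear
    PARAFAC decomposition with core-consistency and split-half rank
    validation, a patch-attention (transformer encoder) classifier for 1-D
    and 2-D spectra alongside k-nearest-neighbour and random-forest
    baselines, exact and sampled Shapley-value feature attribution, and a
    synthetic EEM generator with known ground truth for end-to-end
    validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    pracma,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
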