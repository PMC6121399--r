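Package: mesospat
Title: Spatial Autocorrelation Analysis of Areal Disease Incidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for area-level (province-scale) disease mapping and spatial
    cluster detection, built around the workflow used in registry-based studies
    of malignant mesothelioma incidence: raw morbidity rates from stratified
    case/population tables, fixed-distance-band spatial weights, global spatial
    autocorrelation (Moran's I and the Getis-Ord general G with analytic null
    moments and permutation inference), local cluster statistics (Getis-Ord
    Gi/Gi* hot-spot analysis and Anselin's local Moran with LISA cluster
    typing), Spearman rank correlation with exposure covariates, and a
    synthetic areal-study generator with planted risk clusters for
    power and calibration experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
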