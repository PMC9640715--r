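Package: desitma
Title: High-Throughput DESI-MS Analysis of Tissue Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for generating and analysing high-density tissue
    microarrays (TMAs) screened by automated desorption electrospray
    ionization mass spectrometry (DESI-MS). Provides TMA layout
    construction and stage-coordinate calibration, mzML run ingestion,
    stage-log based assignment of raster-acquired scans to array spots,
    per-spot spectral resampling, averaging, base-peak normalization and
    quality control, per-biopsy profile aggregation, a tandem-MS
    isotope-corrected 2-hydroxyglutarate/glutamate ion-ratio score for
    IDH genotype calling, untargeted lipid profiling (standard normal
    variate normalization, principal component analysis, cross-validated
    classification, loading-based marker ranking), exact-mass lipid
    annotation against a built-in brain-tissue marker panel, and a
    synthetic DESI acquisition simulator with full ground-truth
    manifests for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mzR,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    randomForest,
    xgboost,
    e1071,
    pROC,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
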