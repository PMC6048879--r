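Package: geolink
Title: Linkage of Soil Geochemistry Surveys to Primary Care Records via
    Postcode Exposure Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building residential soil-element exposure estimates
    from multi-density geochemical survey points and linking them to
    primary care patient records by postcode, without disclosing patient
    locations. Implements radius-limited inverse distance weighted (IDW)
    interpolation onto regular rasters with explicit missing-value
    handling, detection-limit based element exclusion, postcode-centroid
    exposure assignment, privacy-preserving within-practice record linkage
    with full match-outcome accounting, and a census-population-weighted
    representativeness validation based on weighted boxplot summaries.
    A synthetic-data generator emulates the survey, postcode, census and
    patient structure so the whole pipeline can be exercised end to end
    with no access to restricted datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
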