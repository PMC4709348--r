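Package: wincrop
Title: Phenology-Based Winter-Crop Mapping and Multi-Period Change Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Maps active winter cropland from multi-date optical satellite
    imagery using the spring-summer contrast in vegetation greenness, and
    quantifies cropland change across epochs. Implements digital-number to
    top-of-atmosphere reflectance conversion with dark-object-subtraction
    (DOS3) atmospheric correction, NDVI maximum-value and median compositing,
    multiresolution region-merging segmentation with zonal statistics and
    water-centroid masking, training-statistics threshold classification with
    terrain (slope) masking, multi-period overlay change accounting, and
    stratified (good-practice) accuracy assessment with adjusted area
    estimates, standard errors, confidence intervals and interval-overlap
    change bounds. Includes a synthetic multi-period scene generator so the
    whole pipeline is testable end to end without satellite archives.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
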