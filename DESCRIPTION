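Package: calciscan
Title: Automated Coronary Calcium Scoring for Non-Gated Chest CT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Automated quantification of coronary artery calcification (CAC)
    in non-contrast, non-ECG-gated chest CT volumes. Candidate lesions are
    extracted by 130 HU thresholding with three-dimensional connected-component
    labeling, described by size, spatial-atlas and multi-scale Gaussian texture
    features, and classified as coronary or non-coronary by a two-stage
    k-nearest-neighbour / support-vector-machine system. Identified
    calcifications are quantified as Agatston score, calcium volume and lesion
    count, and assigned to the five cardiovascular risk strata. The package
    also provides the full agreement-and-reliability statistics suite used to
    evaluate such scoring systems (proportion of agreement, category-shift
    analysis, linearly weighted kappa, two-way intraclass correlation,
    Kendall's W, quartile coefficient of dispersion, and Bland-Altman analysis
    with regression-modelled non-uniform limits), together with a seeded
    synthetic chest-CT phantom generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    RNifti,
    class,
    e1071,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
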