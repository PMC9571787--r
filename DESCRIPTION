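Package: graftmorph
Title: Patient-Specific CT Morphometry of Coracoid Graft Resorption
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies coracoid bone-graft resorption after the Latarjet
    procedure from paired pre-operative and long-term follow-up CT scans.
    Segments bone and metal, reconstructs watertight triangle surfaces,
    rigidly registers the pre-operative scapula to the follow-up scapula with
    trimmed iterative-closest-point, performs a virtual osteotomy to model the
    timepoint-zero graft, isolates the remodelled follow-up graft, measures
    3D volumes and regional resorption, assigns geometric Zhu grades, and
    provides the validation statistics (tie-corrected Kendall tau-b with
    bootstrap confidence intervals, absolute-agreement intraclass correlation)
    together with a synthetic CT phantom generator with exact ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
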