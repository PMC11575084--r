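Package: swellkit
Title: Linear and Volumetric Quantification of Facial Swelling from 3D
    Surface Scans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An automated pipeline for quantifying post-surgical facial
    swelling from longitudinal 3D surface scans. Reads triangle meshes in
    STL, PLY and legacy VTK polydata formats; orients scans into a
    canonical anatomical frame from named landmarks (Frankfurt and
    midsagittal planes); rigidly registers follow-up scans onto the
    baseline with trimmed point-to-surface iterative closest point;
    restricts analysis to an anatomical region of interest bounded by
    landmark-defined planes; computes per-vertex signed surface distances
    (mm) and their region mean; closes open meshes watertight and
    quantifies enclosed-volume differences (mm3) by the divergence
    theorem. Ships a synthetic-scan generator with parametrically known
    swelling for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
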