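Package: mristand
Title: Intensity Standardisation of T1-Weighted MR Brain Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for standardising the intensity scale of T1-weighted
    MP2RAGE-like brain MR volumes to a reference image, so that identical
    tissues are displayed with identical intensities across subjects. Implements
    five standardisation techniques: piecewise linear histogram matching (PHM),
    non-linear (spline) histogram matching (NHM), cumulative histogram matching
    (CHM), ROI-based linear standardisation (RLS) and segmentation-based
    piecewise linear standardisation (SPS), together with the histogram
    machinery they share (robust local-regression smoothing, spline
    parameterisation, GM/WM mode detection, cumulative distributions), a fuzzy
    c-means three-class tissue segmentation, a synthetic brain phantom generator
    with known ground-truth intensity distortions, and a four-level evaluation
    protocol (cumulative-histogram error, voxelwise intensity difference,
    tissue-boundary intensity variation with three-colour transfer functions,
    and maintenance of volume-age correlations) backed by paired nonparametric
    and dependent-correlation statistics (Wilcoxon signed-rank, Pitman-Morgan,
    Steiger's Z, Cohen's q, ICC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    e1071,
    png,
    tibble
Config/testthat/edition: 3
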