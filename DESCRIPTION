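Package: ptcontrast
Title: Probabilistic Tissue Contrast and Morphometry for Contrast-Enhanced Micro-CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies greyvalue contrast in contrast-enhanced micro-CT
    volumes of small animals. Implements the probabilistic tissue contrast
    (PTC), a misclassification-based measure of the overlap between the
    Gaussian greyvalue distributions of two tissues; the simple contrast
    ratio used to track stain progression over staining days;
    threshold-based semi-automatic segmentation within a region of interest
    with voxel-counting morphometrics (volume with voxel-pitch uncertainty
    bounds, cylinder diameter, sheet thickness); and stain-uptake-rate
    estimation from diffusion-front positions or stained-volume
    trajectories. A synthetic phantom generator produces fly-like volumes
    with ground-truth labels, tissue-specific Gaussian greyvalues and a
    time-resolved error-function staining front, so every analysis can be
    validated without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
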