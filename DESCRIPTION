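Package: mbsizer
Title: Optical Sizing and Acoustic Characterization of Microbubble Contrast Agents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the rapid benchtop characterization of lipid-shelled
    microbubble ultrasound contrast agents. Implements an automated brightfield
    segmentation chain (8-bit conversion, Gaussian blur, morphological
    background subtraction, MaxEntropy/Otsu autothresholding, watershed
    declumping, outlier-pixel removal, calibrated particle measurement and
    shape-based filtering), turns the per-image particle tables into pooled
    size distributions with square-root-of-N histogram binning and
    volumetric concentration estimates, and quantifies B-mode echogenicity of
    multi-well phantom images as mean ROI greyscale intensities and decibel
    change after contrast injection. Includes synthetic brightfield and
    B-mode image generators with exact ground truth for validation.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
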