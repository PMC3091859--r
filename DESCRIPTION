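Package: astaxmap
Title: Multispectral Quantification of Astaxanthin in Salmonid Fillets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying the carotenoid pigment astaxanthin in
    salmonid fillets from 19-band multispectral reflectance images.
    Implements maximum noise fraction (MNF) and canonical discriminant
    decompositions with Otsu thresholding for fillet and fat segmentation,
    NIPALS partial least squares regression with leave-one-out
    cross-validation for calibration against chemical reference values, an
    sRGB colour baseline via spectral reconstruction and CIE 1931
    colorimetry, pixel-wise concentration mapping, and a synthetic fillet
    phantom generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    grDevices,
    tiff,
    png,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
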