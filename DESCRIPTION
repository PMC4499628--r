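Package: avaplan
Title: Semiautomatic Aortic Valve Area Planimetry on CT Valve-Plane Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semiautomatic planimetry of the aortic valve area (AVA) on 2D
    contrast-enhanced CT valve-plane images. Detects and crops the Sinus of
    Valsalva, segments the valve orifice with a gradient-vector-flow (GVF)
    active contour initialized from three user seed points at the
    commissures, detects calcifications with a per-image contrast-adaptive
    histogram threshold, and reports the orifice area in cm2 from the pixel
    count and pixel spacing. Includes a synthetic valve-phantom generator
    with known ground truth, readers and writers for DICOM, PNG, TIFF and
    NIfTI images, and Bland-Altman / relative-difference agreement
    statistics for method comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    png,
    tiff,
    RNifti,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
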