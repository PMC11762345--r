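Package: endohsi
Title: Snapshot RGB to Visible-Range Hyperspectral Conversion for Endoscopic Imaging
Version: 0.1.0
Authors@R:
    person("endohsi", "maintainers", email = "endohsi@example.org", role = c("aut", "cre"))
Description: Converts conventional 8-bit RGB endoscopy frames into
    visible-range (380-780 nm, 401 band) hyperspectral reflectance cubes
    using a 24-patch colour-target calibration: sRGB linearisation, CIE XYZ
    conversion, polynomial error correction of the camera response fitted by
    Moore-Penrose pseudoinverse, and spectral reconstruction through a
    6-component PCA basis combined with multiple regression. Includes
    simulated narrow-band imaging (415/540 nm) renderings, ENVI and archive
    cube I/O, a synthetic camera/spectrometer simulator for fully
    self-contained calibration experiments, and an object-detection
    evaluation layer (IoU matching with a background class, confusion
    matrices, sensitivity/precision/F1/accuracy/kappa, average precision)
    for YOLO-format annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    jpeg,
    MASS
Config/testthat/edition: 3
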