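Package: ATWquant
Title: Average Temperature Weight Quantification of Class-Activation Heat
    Maps and Seedling-Detection Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies Grad-CAM style class-activation heat maps of crop
    seedling detectors with the Average Temperature Weight (ATW) statistic:
    each foreground pixel is assigned to the nearest of four reference color
    families (red, yellow, green, blue) by the CIEDE2000 color difference in
    CIELAB space, given an interpolated temperature weight within the family
    band, and the weights are averaged. Ships the supporting detection
    evaluation calculus (IoU matching, precision, recall, F1, AP50, field
    miss/false accounting), YOLO-format label I/O with dataset splitting and
    bounding-box-aware augmentation (affine, color distortion, Gaussian
    noise, Cutout, Mosaic, environmental presets), seeded synthetic fixture
    generators for heat maps and detection scenarios, and closed-form model
    arithmetic (GhostConv compute/parameter ratios, cosine-annealing
    learning-rate schedule). A command-line entry point wires all tools.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    jsonlite,
    yaml,
    optparse
Suggests:
    farver,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
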