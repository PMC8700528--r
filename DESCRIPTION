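Package: cvmstage
Title: Automatic Cervical Vertebral Maturation Staging from Cephalometric Landmarks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automatic cervical vertebral maturation (CVM) assessment from
    lateral cephalograms. Reads LabelMe point annotations of the C2-C4 vertebrae,
    derives millimetre calibration from a 10 mm reference marker, computes the five
    morphometric quantities (lower-border concavity depths of C2-C4 and base-to-
    anterior-height ratios of C3/C4), assigns the Baccetti stages CS1-CS6 through a
    thresholded decision workflow, and evaluates agreement with gold-standard staging
    (per-stage precision, recall, specificity, F1, overall accuracy, Cohen's kappa,
    intraclass correlation) and landmark placement error in millimetres. Includes a
    stage-conditioned synthetic generator of vertebral outlines and radiograph-like
    images with exact ground truth, and a compact convolutional landmark regressor
    (coordinate regression trained with Adam on a squared-error objective) so the full
    label-measure-stage-evaluate pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
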