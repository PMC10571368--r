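Package: dynroot
Title: Dynamic-Threshold Segmentation of Isolated Tooth Roots and Root
    Surface Area from CBCT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computer-aided segmentation of isolated tooth roots in 8-bit
    cone-beam computed tomography (CBCT) volumes using a personalized
    dynamic intensity threshold.  A tooth is binarized against air,
    labelled as a 3D connected component, and its surface (edge) pixels
    are extracted slice by slice with an 8-neighbourhood rule.  The
    intensity histogram of those surface pixels is bimodal (cementum vs.
    enamel); the valley between the first peak and the crown peak is the
    per-tooth segmentation threshold, and the root surface area (RSA)
    follows by summing per-slice root perimeters times the slice spacing.
    Includes a minimal DICOM series reader, a portable raw-volume fixture
    format, synthetic tooth phantoms with analytic ground truth,
    method-comparison statistics (paired t-test, Bland-Altman limits of
    agreement, Cronbach's alpha, ICC(2,1)), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    png,
    stats,
    grDevices,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
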