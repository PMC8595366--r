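Package: polarflip
Title: Quantitative Imaging Analysis of Optogenetic Front-Rear Polarity
    Reversal in Channel-Confined Migrating Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of two-channel fluorescence time-lapse
    stacks of single neutrophil-like cells migrating in straight
    microfluidic channels under targeted optogenetic stimulation: camera
    and empirical FRET ratio-bias correction, background estimation and
    Otsu-based cell segmentation, overlap tracking and loess-smoothed
    kinematics, front/middle/rear subcellular activity quantification,
    length-normalized rear-registered kymographs, interpolated
    event-onset detection (rear response, front response, stalling,
    activity cross-point), stratification of stimulation responses, a
    center-stimulation responder-fraction estimator, and the cohort
    statistics used alongside (rank-sum, exact contingency tests,
    binomial intervals, correlation).  Includes a seeded synthetic
    microscopy generator with full ground truth so every stage is
    verifiable without raw microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
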