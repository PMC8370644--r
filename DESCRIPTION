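Package: wristbold
Title: Simulation and Four-Arm Analysis of Wrist Extension Versus Flexion BOLD fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether task fMRI can differentiate brain
    activity driving wrist extension from wrist flexion. Provides a
    synthetic-BOLD generator reproducing a mixed blocked/event motor
    design (15-cue blocks, 6/8/10 s onset asynchronies, 15 s rests,
    TR 3 s) with known spatial activation structure, plus the four
    analysis arms used on such data: mass-univariate GLM contrast
    mapping with permutation cluster-extent correction, multi-voxel
    pattern analysis (mutual-information feature ranking and linear
    SVM under stratified 10-fold cross-validation), winner-take-all
    action labeling with between-subject probability maps and Jaccard
    overlap, and percent-signal-change action dominance with a
    binomial reproducibility null. Every stage is testable against
    the generator's ground truth without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    e1071,
    pROC,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
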