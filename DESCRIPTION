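Package: opaxr
Title: Uncertainty-Aware Classification of Bilateral Pulmonary Opacities
    on Chest Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Training and evaluation framework for detecting bilateral
    pulmonary opacities -- the radiographic hallmark of acute respiratory
    distress syndrome -- on single-view chest radiographs, with explicit
    modelling of the 'equivocal' class. Implements a three-class training
    scheme whose equivocal images receive the soft probability target
    (0.5, 0.5, 1) over (absent, present, equivocal), alongside standard
    cross-entropy, label-smoothed and focal losses; a from-scratch small
    convolutional network with analytic backpropagation and Adam so the
    full pipeline runs on a plain CPU; synthetic chest phantoms with three
    simulated annotators and majority/disagreement adjudication; diagnostic
    metrics (precision, sensitivity, specificity, balanced accuracy,
    diagnostic odds ratio, AUROC, AUPRC) with percentile bootstrap
    confidence intervals; confidence binning and maximum calibration error
    with reliability-diagram tables; Grad-CAM and occlusion sensitivity
    maps; and a rule-based radiology-note labeler with negation,
    uncertainty and laterality handling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
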