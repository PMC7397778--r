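Package: Ki67Adapt
Title: Domain-Adaptive Nucleus Detection and Classification for Ki-67 IHC Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cycle-consistent adversarial image translation and proximity-map
    regression for joint nucleus detection and three-class classification
    (immunopositive tumor, immunonegative tumor, nontumor) in Ki-67
    immunohistochemistry images. Includes a synthetic two-domain image
    generator with exact point ground truth, a compact CPU convolutional
    network engine, eta-threshold/local-maxima post-processing, Hungarian
    one-to-one matching, precision-recall evaluation with AUC over the
    suppression-threshold sweep, and orchestration of the four training
    regimes (source-only baseline, adapted, mixed, target-supervised).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, Rcpp, png, jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
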