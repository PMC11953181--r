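Package: duralseg
Title: Dural Sac Segmentation and Lumbar Canal Stenosis Assessment on CT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: End-to-end toolkit for automated assessment of lumbar central
    canal stenosis on computed tomography. Generates synthetic spine-CT
    phantoms with analytically known dural-sac geometry, locates vertebral
    centroids and fits a virtual spinal curve, reformats disc levels into
    stacks of slices perpendicular to the curve, trains a semi-supervised
    single-encoder dual-decoder U-Net (cross-entropy on labeled slices plus
    an L2 cross-decoder consistency penalty on unlabeled slices), measures
    dural-sac cross-sectional area from predicted masks, classifies stenosis
    against the 100 mm2 and 75 mm2 thresholds with the narrowest-slice rule,
    and evaluates agreement with Dice, intraclass correlation, and exact
    binomial confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
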