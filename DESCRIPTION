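Package: wrinklefind
Title: Nasolabial Wrinkle Line Detection with Hessian Ridge Filtering and
    Active Appearance Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects the nasolabial wrinkle line on face images as a
    20-point landmark curve. A Hessian eigenvalue ridge filter extracts
    candidate dark curvilinear valleys in the cheek region, short and
    distorted lines are discarded by length and turning-angle thresholds,
    and the surviving line seeds a per-image unique initial shape for a
    fixed-Jacobian steepest-descent Active Appearance Model fit. Includes
    generalized Procrustes alignment and PCA shape models, an L1-regularized
    sparse shape projection, a deterministic synthetic skin-image fixture
    generator with ground-truth landmarks, and Jaccard-index evaluation of
    detected wrinkle lines against manual annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
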