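Package: featfuse
Title: Deep-Feature Ensemble Classification for Brain MR Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for classifying 2-D brain magnetic
    resonance images from banks of fixed feature extractors. Images are
    cropped to the extreme points of the largest foreground contour,
    resized by bicubic interpolation and optionally augmented with the
    eight dihedral rotation/flip variants. Per-extractor feature tables
    are scored against a bank of nine classifiers (softmax head, Gaussian
    naive Bayes, AdaBoost, k-nearest neighbours, random forest, support
    vector machines with linear/sigmoid/RBF kernels, and an extreme
    learning machine solved by Moore-Penrose pseudoinverse), the
    resulting evaluation matrix drives a top-3 selection rule with a
    standard-deviation tie-break and a homogeneous-family exclusion, and
    the selected features are concatenated into pair and triple
    ensembles. Synthetic phantoms and synthetic feature banks make every
    stage testable without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    jsonlite,
    png,
    randomForest,
    rpart,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    nnet,
    RNifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
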