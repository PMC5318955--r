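Package: ihcnorm
Title: Inter-Batch Normalisation of Immunohistochemistry Images by Blind
    Colour Deconvolution
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Normalises brightfield immunohistochemistry (IHC) images across
    staining batches.  RGB images are transformed to staining darkness (an
    optical-density-like quantity), per-batch hematoxylin and DAB colour
    vectors are extracted blindly by one of five unsupervised methods
    (PCA/angle-quantile, HSV-clustering initialisation, NMF, and sparse NMF
    variants), batches are aligned by colour matching in the deconvoluted
    stain space, and residual intensity drift can be corrected by monotone
    per-channel distribution fitting (P99 rescaling, quantile matching,
    linear or penalised B-spline quantile regression).  Quality control is
    quantile-quantile based (RMSE against the identity line, two-sample
    Kolmogorov-Smirnov statistics), and staining is quantified per tissue
    core as Labelling Index and Quick Score.  A synthetic two-stain image
    generator with known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    graphics,
    utils,
    png,
    tiff,
    jsonlite,
    mgcv,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
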