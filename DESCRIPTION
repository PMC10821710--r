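Package: im2im
Title: Configurable Microscopy Image-to-Image Transformation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A configurable framework for microscopy image-to-image
    transformation: one axis-labelled image model and one training and
    inference engine shared by supervised pixel regression (FCN),
    conditional adversarial translation (pix2pix), unsupervised
    cycle-consistent translation (CycleGAN) and embedding-based instance
    segmentation (EmbedSeg-type).  Includes microscopy-specific intensity
    normalization (percentile, standard and Z-center), Reinhard-style
    stain normalization for histology tiles, weighted patch sampling with
    exclusion masks, anisotropic 3D U-Net backbones, Gaussian-blended
    sliding-window inference on up-to-5D images, evaluation metrics
    (Pearson, SSIM, PSNR, pixel F1, average precision at IoU 0.5) and a
    seeded synthetic-data generator so every pipeline is trainable and
    testable at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tiff,
    yaml,
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
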