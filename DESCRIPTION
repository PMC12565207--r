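Package: msseg3d
Title: Lesion-Aware Patch Sampling and Efficient 3D Convolutional
    Segmentation of Multiple Sclerosis Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end, CPU-only framework for volumetric multiple sclerosis
    (MS) lesion segmentation from multi-modal MRI (T1, T2, FLAIR). Provides
    NIfTI ingestion and subject validation, z-score normalisation over
    non-zero voxels, patient-level cohort splitting, a synthetic multi-modal
    brain phantom generator with calibrated sparse lesion prevalence,
    lesion-aware balanced patch sampling with a joint image/mask augmentation
    suite, an inverted-bottleneck (MBConv3D) EfficientNet3D-UNet and a
    baseline 3D U-Net built from declarative specifications with
    hand-written forward/backward passes, composite Dice + binary
    cross-entropy training with Adam, cosine-annealed learning rates and
    early stopping, sliding-window whole-volume inference, small-blob
    suppression, and Monte-Carlo dropout / deep-ensemble uncertainty maps
    with expected calibration error reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
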