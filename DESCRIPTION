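Package: neurofuse
Title: Voxel-Wise Intensity Projection and Multimodal 3D CNN
    Classification of Brain MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for summarising stacks of resting-state intrinsic
    connectivity network (ICN) spatial maps into voxel-wise intensity
    projections (the maximum, the absolute minimum, and the maximum
    absolute value across components), fusing them with gray-matter
    density volumes into multi-channel model inputs, and classifying
    subjects (Alzheimer's disease, mild cognitive impairment, cognitively
    normal) with a multi-channel 3D convolutional neural network in the
    AlexNet-with-dropout lineage.  Includes ALFF and fALFF spectral
    baselines, stratified repeated-subsampling cross-validation with
    plateau learning-rate scheduling and early stopping, fold-level
    metric aggregation, chi-squared model comparison, guided
    backpropagation saliency with Gaussian smoothing and cohort
    averaging, and a synthetic cohort generator so that the full pipeline
    runs end-to-end without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    pROC,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
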