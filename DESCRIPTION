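Package: cfcnn
Title: Central Focused Convolutional Neural Networks for Lung Nodule
    Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-classification segmentation of lung nodules in CT
    volumes with a two-branch convolutional neural network built around a
    central pooling layer: max pooling with position-dependent 1-D kernel
    sizes that preserves feature resolution near the patch centre. Includes
    tri-slice and multi-scale 2-D patch extraction, distance-transform
    weighted training-voxel sampling for class imbalance, bidirectional
    slice-propagation 3-D post-processing, segmentation metrics (Dice,
    Jaccard overlap, sensitivity, positive predictive value, symmetric
    average surface distance), multi-rater consensus ground-truth fusion,
    and a synthetic CT nodule phantom generator so the full pipeline runs
    end-to-end without clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
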