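Package: wingbeat
Title: Wingbeat-Resolved Kinematics and Motor Cortical Population Analysis
    for Free Flight
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for synchronized 3D trajectory, pose-keypoint,
    accelerometer and spike-train recordings from freely flying animals.
    Segments flights and clusters them into reproducible paths, detects
    wingbeat cycles from the dorsoventral accelerometer and assigns a
    continuous wingbeat phase, extracts stroke envelopes and left-right
    asymmetries, and quantifies flight-to-flight reproducibility. On the
    neural side it provides circular-shift modulation tests, spike-phase
    locking statistics with permutation nulls and false-discovery-rate
    control, binary wingbeat "barcode" construction with support-vector
    decoding of wingbeat groups, per-wingbeat Poisson encoding models with
    elastic-net feature selection, and population dimensionality estimates
    via PCA, demixed PCA and Gaussian-process factor analysis with
    leave-one-neuron-out model selection. A fully deterministic synthetic
    session generator with planted ground truth supports end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    glmnet,
    e1071,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
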