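Package: ctless
Title: Transmission-Less Attenuation Compensation for Myocardial Perfusion SPECT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Scatter-window and deep-learning based attenuation compensation
    for myocardial perfusion SPECT without a transmission scan, together with
    a task-based evaluation framework. Provides synthetic anthropomorphic
    torso phantoms, an attenuated parallel-beam projector with
    collimator-detector response and Poisson noise, OSEM reconstruction with
    and without attenuation compensation, a multi-channel-input multi-decoder
    3-D segmentation U-net with attention-gated skip connections that
    partitions the scatter-window reconstruction into attenuation regions,
    piecewise-constant attenuation-map assembly, projection-domain perfusion
    defect insertion, a channelized Hotelling observer with rotationally
    symmetric frequency channels, and clustered ROC/AUC statistics with
    non-inferiority testing and fidelity metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
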