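Package: yolobt
Title: Adaptive Bad-Trial Detection in Rendered EEG Waveform Images
Version: 0.1.0
Authors@R:
    person("EEG QC", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Quality control for event-related potential (ERP) studies by
    object detection on rendered multichannel EEG waveform screens.
    Implements the YOLOBT one-stage detector: a small-variant CSP backbone
    augmented with cross-layer attention bottlenecks (CLAB), a hierarchical
    feature guidance module (HFGM) replacing interpolation upsampling in the
    top-down fusion path, and a global information classification module
    (GICM) that gates the detection head on global signal quality so that
    artifact tolerance adapts to the overall noise level of a recording.
    Ships a calibrated synthetic EEG screen generator with four artifact
    classes and peak-to-peak severity bands, a waveform renderer emitting
    YOLO-format labels, training and inference for the detector, forward-pass
    profiling (parameters and GFLOPs), and VOC-style evaluation metrics with
    severity-stratified reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
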