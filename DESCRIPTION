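Package: mudetect
Title: Movement Detection from Multi-Unit Intracortical Recordings
Version: 0.1.0
Author: Package Author
Maintainer: Package Author <author@example.org>
Description: Detects self-paced forelimb movements ("paddle hits") from
    multi-channel extracellular recordings of multi-unit activity in rat
    primary motor cortex. Implements discrete-wavelet soft-threshold
    denoising with a quantile-quantile noise estimate, adaptive
    median-based spike detection with a refractory period, windowed
    spike-count feature extraction around behavioral events, and
    quadratic discriminant classification of pre-movement versus
    background epochs with stratified five-fold cross-validation. A
    synthetic-session generator reproduces the statistical structure of
    the recordings (rate-modulated multi-unit spike trains, stationary
    and burst noise, the three-hit trial protocol) so that every stage
    of the pipeline can be validated against ground truth.
License: MIT
Encoding: UTF-8
Imports: Rcpp, jsonlite, signal, stats, utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), MASS, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
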