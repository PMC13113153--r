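Package: emglab
Title: Surface EMG Simulation, Acquisition-Parameter Sweeps, and Classifier Benchmarking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A workbench for one-dimensional surface electromyography (EMG)
    signal processing. Provides a reproducible synthetic EMG generator
    (band-limited colored noise amplitude-modulated by Gaussian burst
    envelopes, with powerline, drift, spike and thermal-noise artifacts),
    acquisition-channel models (uniform midtread quantization and
    Kaiser-windowed polyphase rate conversion) with mean-squared-error
    sweeps over bit depth, sampling rate and window geometry,
    Hudgins-style time-domain feature extraction with a composite
    percentile/zero-crossing auto-labeler, an analytic neural-network
    shape-inference and parameter-counting engine, stratified
    cross-validated benchmarking of standard classifiers, and a
    single-step Markov-decision-process formulation of window
    classification with a small deep-Q-network agent.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    class,
    rpart,
    randomForest,
    e1071,
    xgboost,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
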