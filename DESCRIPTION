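Package: deepHAR
Title: Deep Convolutional LSTM Networks for Wearable-Sensor Activity Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Human activity recognition from multichannel wearable-sensor
    time series with a hybrid deep network that stacks temporal (valid,
    no-padding) convolutions over a two-layer peephole-LSTM recurrent stage
    and a softmax output, together with an equally sized non-recurrent
    baseline CNN. Provides sliding-window segmentation with last-sample
    labelling, per-channel linear interpolation of missing samples and [0,1]
    normalisation, mini-batch RMSProp training with orthogonal
    initialisation and inverted dropout, hand-derived exact gradients,
    class-imbalance-aware evaluation (sample-weighted F1 with or without
    the Null class), a seeded generator of wearable-like labelled sensor
    streams (modality groups, dominant Null class, time-mirrored gesture
    pairs), and plain-text recording/checkpoint I/O with a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    caret,
    e1071,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
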