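Package: fedherd
Title: Federated CNN-LSTM Stress Monitoring for Livestock Sensor Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulation of privacy-preserving stress detection in
    dairy cattle from wearable multimodal sensor streams. Generates seeded
    synthetic herds (heart rate, body temperature, activity, environment, GPS)
    with controllable stress episodes and sensor faults; implements the
    standard edge preprocessing pipeline (forward/backward fill, z-score
    outlier removal, min-max normalization, 30-minute rolling features,
    threshold proxy labels); trains a hybrid CNN-LSTM binary classifier with
    hand-derived backpropagation-through-time and Adam; orchestrates
    sample-size-weighted federated averaging (FedAvg) over non-IID per-animal
    client partitions with a per-round communication ledger; and evaluates
    federated against centralized training with standard classification
    metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    zoo,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    caret,
    optparse
Config/testthat/edition: 3
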