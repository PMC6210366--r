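Package: odorprint
Title: Odor Fingerprint Feature Mining for Electronic-Nose Sensor Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Feature-mining pipeline for metal-oxide gas-sensor (electronic
    nose) array recordings: relative-difference drift suppression, fused
    time-domain (per-channel mean) and frequency-domain (mean of wavelet
    packet leaf-coefficient variances) odor-fingerprint features, PCA and
    PLS-DA variable-importance-in-projection (VIP) feature selection with
    nested subset generation, Kennard-Stone sample partitioning, and
    classification by random forest and a probabilistic neural network
    (Parzen kernel Bayes classifier), together with a seeded synthetic
    sensor-array simulator and a deterministic end-to-end pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
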