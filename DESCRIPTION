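Package: vstream
Title: Ventral-Stream Population Coding Analysis Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis pipeline for multi-area extracellular
    recordings from the visual ventral stream: Poisson-null responsiveness
    and recording-stability QC, receptive-field mapping from local sparse
    noise with circular-Gaussian fits, orientation and spatial-frequency
    tuning, texture-versus-noise modulation and divergence latency,
    axis-model encoding of responses in a reduced deep-feature space,
    population decoding of feature principal components with
    retrieval-based image reconstruction, face-selectivity scoring,
    identity decoding with Gaussian naive Bayes, and view-invariance
    indices. Includes a synthetic-data generator (stimulus schedules,
    procedural image banks, a deterministic Gabor feature extractor, and
    an inhomogeneous-Poisson spiking model) so every stage is testable
    without recorded data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
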