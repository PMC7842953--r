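Package: oncnmfe
Title: Online CNMF-E Source Extraction for 1-Photon Microendoscopic
    Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Streaming extraction of neuronal spatial footprints and
    denoised calcium traces from 1-photon microendoscopic (miniscope)
    imaging movies. Implements an online variant of the CNMF-E matrix
    factorization with a ring-structured autoregressive background model,
    OASIS deconvolution of calcium traces under AR dynamics, online
    detection of newly active neurons from a residual buffer with
    incrementally updated correlation and peak-to-noise summary images,
    rigid online motion correction, and an alternative convolutional
    ("ring-CNN") background model trained with a quantile loss. Includes
    a synthetic-movie simulator with ground truth, component registration
    via the Hungarian algorithm with F1 scoring, movie and results I/O
    (multi-page TIFF, HDF5), YAML configuration with per-dataset presets,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tiff,
    rhdf5,
    yaml,
    jsonlite,
    clue
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
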