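Package: strfens
Title: Learning and Characterizing Ensembles of Auditory Spectro-Temporal
    Receptive Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns ensembles of auditory spectro-temporal receptive fields
    (STRFs) by projected gradient ascent on either a sustained-firing
    (temporal slowness) objective or a population-kurtosis (sparse coding)
    objective, under response-decorrelation or filter-shape orthonormality
    constraints. Includes a synthetic natural-sound-like stimulus generator,
    a simplified peripheral auditory model producing log-frequency auditory
    spectrograms, patch extraction with PCA whitening, per-filter
    characterization (separability, modulation transfer functions, best
    rate/scale, directionality, compactness), ensemble-level analyses
    (ensemble MTFs, activation persistence, population response histograms,
    symmetric KL comparison), and normalized spectral clustering of receptive
    fields into canonical classes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
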