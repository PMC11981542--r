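Package: aukprop
Title: Atmospheric Propagation and Vocal Individuality of Seabird Calls
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models how individual-identity information in seabird social
    calls survives atmospheric propagation. Implements ISO 9613-1 atmospheric
    absorption, spherical-spreading attenuation of calibrated waveforms to a
    log-spaced distance grid under monthly meteorological conditions,
    end-to-end sound-level calibration (apparent sound pressure levels and
    1-m source levels), extraction of a 15-parameter bioacoustic feature set,
    and individuality statistics: Kaiser-Meyer-Olkin adequacy, principal
    components with Kaiser retention, nested permuted discriminant function
    analysis, supervised-embedding support-vector classification, and
    Beecher's information statistic with its distinguishable-individuals
    interpretation. A synthetic-call generator with known ground truth makes
    the whole pipeline testable without field recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    e1071,
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    cluster
Config/testthat/edition: 3
RoxygenNote: 7.3.3
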