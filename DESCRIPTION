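Package: twotone
Title: Two-Tone (Mooney) Image Pipelines for Studying Perceptual
    Reorganization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building and analysing two-tone (Mooney) image
    experiments: stimulus synthesis (Gaussian smoothing plus luminance
    binarization, catch images, grayscale-to-two-tone morph sequences),
    low-level image statistics (Sobel edge density, and contrast energy
    and spatial coherence as Weibull summaries of centre-surround
    contrast distributions), region-of-interest based scoring of
    touchscreen naming and pointing responses with a local/global error
    taxonomy, a seeded synthetic-cohort generator with crossed
    participant and image random effects, and a multilevel inference
    layer (crossed random-intercept logistic and log-distance models,
    likelihood-ratio tests, Wald contrasts, bootstrapped confidence
    intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    MASS,
    jsonlite,
    yaml,
    png,
    stats,
    utils
Suggests:
    mgcv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
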