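Package: mpsize
Title: Genome Length Determination in AAV Vectors by Mass Photometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for determining the encapsidated genome length of
    adeno-associated virus (AAV) vectors from mass photometry (MP)
    landing-event data. Provides kernel-density smoothing and Gaussian
    peak fitting of ratiometric-contrast event lists, six linear
    contrast-to-size calibration families (protein mass, dsDNA, RNA,
    circular ssDNA plasmids, and AAV-based delta-contrast and
    absolute-contrast calibrations) with leverage diagnostics, three
    sizing approaches (empty/filled contrast difference, AAV-based
    calibration, and sizing of the released genome), study-level
    aggregation (accuracy, coefficient of variation), an
    approach-recommendation decision tree, and a seeded simulator of MP
    landing-event data for fully reproducible end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'events-io.R'
    'peaks.R'
    'calibration.R'
    'sizing.R'
    'simulate.R'
    'benchmark.R'
    'pipeline.R'
    'show-methods.R'
    'mpsize-package.R'
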