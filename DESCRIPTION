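Package: plinet
Title: Phase Lag Index Functional Brain Networks from Resting-State EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds weighted functional brain networks from multichannel
    resting-state EEG. Recordings are downsampled, Butterworth band-pass
    filtered, segmented into overlapping epochs and decomposed into the
    classical theta/alpha1/alpha2/beta rhythms; pairwise coupling is
    quantified with the Phase Lag Index (PLI) on Hilbert instantaneous
    phases; proportionally thresholded weighted graphs are characterised by
    the weighted clustering coefficient, characteristic path length and the
    small-world index sigma against degree-preserving Maslov-Sneppen
    surrogates; and two subject groups are compared edgewise and
    metric-wise with one-way ANOVA. A seeded synthetic-cohort generator
    with controllable pairwise phase-lag coupling provides ground truth for
    validating every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
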