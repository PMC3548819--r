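Package: fdsearch
Title: Facilitated-Diffusion Target Search of Transcription Factors in
    Bacterial Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Semi-analytical model of the in vivo target search of a
    bacterial transcription factor within the facilitated diffusion
    framework. The genome is coarse-grained into a confined closed
    self-avoiding walk of DNA 'blobs' on a lattice spanning the nucleoid,
    a lattice random walk supplies first-passage and return statistics for
    the searcher, and closed-form blob-level kinetics (binding and escape
    splitting probabilities and conditional times, one-dimensional sliding
    with dissociation) assemble into the mean search time, its three
    contributions, and the fraction of time spent non-specifically bound.
    Includes calibration of the association rate against a measured bound
    fraction, rate sweeps and minimisation, local (colocalised) searches,
    and independent stochastic and linear-algebra oracles for every closed
    form.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
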