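Package: halomet
Title: Halide-Depletion Comparative Metabolomics and Molecular Networking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery workflow for halogenated natural products and products of
    cryptic halogenation by halide depletion: paired-condition differential
    feature statistics on LC-MS feature tables (noise-floor gap filling,
    fold changes, two-tailed Student's t-tests), chlorine detection from MS1
    isotope envelopes (M+2 isotopologue ratio), exact-mass molecular formula
    decomposition with an RDBE plausibility filter, modified-cosine molecular
    networking of MS/MS spectra (fragment and neutral-loss matching), and
    stable-isotope label incorporation fitting by non-negative least squares.
    Includes a seeded synthetic LC-MS experiment generator emulating a
    two-condition (halide-replete vs depleted) design so the entire pipeline is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
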