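Package: tomohelix
Title: Helical Reconstruction and Sub-Tomogram Averaging for Cryo-Electron Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: In situ structural analysis of filamentous and globular
    macromolecules in cryo-electron tomograms. Implements iterative helical
    reconstruction of cytoskeletal filaments from 2D-projected sub-tomogram
    segments (projection matching, weighted back-projection, helical
    rise/twist refinement, per-filament polarity voting) and generic
    sub-tomogram averaging with reference-based classification and
    difference-density detection of additional features such as rRNA
    expansion segments. Ships a synthetic-tomogram generator (helical
    filaments with configurable rise/twist, globular particle fields,
    single-axis missing wedge, additive noise at a set signal-to-noise
    ratio) so that every stage can be validated against exact ground truth,
    plus MRC2014 volume and STAR metadata table I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
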