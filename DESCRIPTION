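Package: gravatt
Title: Gravitational Model of Visual Attention Scanpaths
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates human visual attention scanpaths on static images with a
    gravitational model: low-level feature activations (intensity, colour and
    orientation gradients) act as attracting masses, and the focus of attention
    is a unit mass moving in their inverse-square field under damped Newtonian
    dynamics, with a dynamic inhibition-of-return field that discounts
    already-visited locations. Includes a winner-take-all baseline, a
    velocity-threshold fixation detector, scanpath similarity metrics
    (string-edit distance, time-delay embeddings, scaled time-delay embeddings),
    the NSS saliency score with grid-search parameter tuning, and a synthetic
    stimulus/observer generator for fully reproducible benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    jpeg,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
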