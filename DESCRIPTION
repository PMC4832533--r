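Package: dupliclass
Title: Classification of Duplicate Gene Retention Mechanisms from
    Expression Profiles
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genome-wide classification of the evolutionary mechanisms
    retaining duplicate gene pairs (conservation, neofunctionalization,
    subfunctionalization, specialization) by comparing relative expression
    profiles of each duplicate pair in one species against the profile of
    its ancestral single-copy gene in a sister species.  Euclidean
    distances between relative expression profiles are compared with an
    expression-divergence cutoff calibrated from the distance distribution
    of single-copy orthologs (default: median plus semi-interquartile
    range).  Includes a seeded synthetic-data generator with ground-truth
    mechanism labels for validating the classifier end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
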