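Package: multistem
Title: Volume-Based Allometric Model of Multi-Stemmed Shrubs Versus Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements a volume-based allometric growth model that contrasts
    multi-stemmed shrubs with single-stemmed trees of equal above-ground woody
    volume. Stems and branches are idealised as truncated cones (cylinders at
    the tip-radius floor) assembled by a recursive branching rule; plant height
    is recovered from volume by monotone root finding, and the two growth forms
    are compared on basal cross-sectional area, bark (epidermis) surface area,
    sprouting area, and twig counts. A biomechanics component integrates the
    gravity-loaded bending moment of straight and uprising tapered stems, and
    a packaged literature table supports a vote-count of the empirical evidence
    for the faster-growth prediction. Includes a command-line interface for
    reproducible comparison tables and curve exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
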