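Package: slopetraits
Title: Root Trait Analysis and Multi-Criteria Scoring of Slope-Stabilising Plant Species
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ranking plant species as ecological engineers for
    fixing soil on unstable slopes. Computes root architectural traits
    (individual soil volume and its per-layer distribution, root area ratio
    by depth, slope sector and diameter class), root mechanical traits
    (maximal tensile stress, ultimate strain, power-law strength-diameter
    fits, second moment of inertia, bending modulus and rigidity from
    force-displacement records) and soil physical traits (gravimetric water
    contents, dry bulk density, Mohr-Coulomb cohesion and friction angle
    from direct-shear records). Trait values are converted to 1/2/3
    performance scores and combined with a non-associative pairwise
    synthesis rule into per-property global scores and hotspot placement
    recommendations. A synthetic-data module generates every input record
    type from species root-system archetypes so the full pipeline is
    testable without field data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
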