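Package: phytomer3d
Title: Geometric Modeling and Architecture Quantification of Wheat from 3D Phytomers
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building three-dimensional geometric models of wheat
    shoots from digitized phytomer data. Reads contact-digitizer point traces
    (leaf surface rows in the 3n+1 convention, vein polylines, stem node and
    girth points), normalizes phytomers into reusable templates, assembles
    tillers and whole shoots with rigid transforms, extracts multi-scale
    phenotypic traits (blade curvature, stem-leaf angle, phytomer envelope,
    internode lengths, stem inclination, plant height, spike-layer projected
    area), and summarizes plant architecture as the vector PA = (C, L, PHY, S)
    with loose / semi-compact / compact classification. Includes a synthetic
    plant generator with analytically known ground truth, a phytomer template
    database, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
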