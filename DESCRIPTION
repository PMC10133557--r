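Package: cdmbone
Title: Continuum-Damage Finite-Element Simulation of Cortical Bone Compression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale continuum-damage-mechanics simulation of axial
    compression of a cortical bone diaphysis segment.  Provides a synthetic
    voxel specimen generator emulating a hollow tubular cortical shell,
    voxel-conforming eight-node hexahedral meshing, a transversely isotropic
    elastic material with an exponential strain-driven scalar damage law,
    two strain-judging criteria for damage initiation (minimum principal
    strain and von Mises equivalent strain), an incremental staggered
    progressive-failure solver with element failure and percolation
    detection, and post-processing of fracture load, apparent stiffness and
    crack-orientation class, including mesh-sensitivity and
    criterion-comparison studies.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
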