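Package: wellTFM
Title: Three-Dimensional Traction Force Microscopy in Micropatterned
    Cylindrical Wells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes three-dimensional cell-generated traction forces in
    cylindrical microwells molded into linearly elastic polyacrylamide
    hydrogels (3D micropatterned traction force microscopy). From paired
    confocal bead stacks (deformed and relaxed states) the pipeline measures
    3D gel displacements by volumetric particle image velocimetry, corrects
    the axial focal shift caused by refractive-index mismatch, reconstructs
    surface tractions by an inverse finite-element method with mechanical
    equilibrium built in, and reports unfolded cylindrical traction maps,
    circumferential profiles and summary force metrics. A synthetic
    bead-stack and forward-model generator makes every stage testable
    without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
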