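Package: codedpty
Title: Coded-Surface Lensless Ptychography with Virtual Error-Bin States
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and reconstruction toolkit for coded-surface lensless
    ptychography of label-free biological samples. Provides band-limited
    angular-spectrum wave propagation and digital refocusing, a forward
    simulator with partially coherent (mixed-state) illumination and
    controllable artifact injection, an iterative mixed-state reconstruction
    engine with a virtual error-bin state that drains model-mismatch artifacts
    out of the object estimate, Brenner-gradient autofocus and tile-wise
    height mapping, two-wavelength deep-ultraviolet Beer-Lambert unmixing into
    quantitative protein and nucleic-acid mass maps, deterministic virtual
    fluorescence and H&E-like staining, and label-free cytometric feature
    extraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    tiff,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
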