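Package: stenoPIV
Title: Echo Particle Image Velocimetry and Shear-Stress Analysis of Stenotic Flow Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully synthetic testbed for ultrasound particle
    image velocimetry (Echo PIV) of pulsatile flow through stenosed vessel
    phantoms. Provides a parametric stenosis geometry, a pulsatile pump
    waveform and a rigid-wall incompressible Navier-Stokes reference solver
    (stream-function-vorticity formulation on a wall-fitted grid), a
    microbubble particle-image generator with exact ground-truth motion, a
    multi-pass window-deformation PIV engine with Gaussian sub-pixel peak
    fitting and robust vector validation, and shear-stress / wall-shear-stress
    extraction along the plaque surface, together with pipeline orchestration
    for severity sweeps comparing PIV measurements against the solver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Matrix,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'geometry.R'
    'flowfields.R'
    'solver.R'
    'synthetic.R'
    'piv.R'
    'shear.R'
    'pipeline.R'
    'io.R'
    'plots.R'
    'stenoPIV-package.R'
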