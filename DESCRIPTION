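Package: xfetsim
Title: Simulation and Contrast Analysis for X-Ray Fluorescence Emission
    Tomography and Fan-Beam CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward simulation and image-quality analysis for X-ray
    fluorescence emission tomography (XFET) of gold nanoparticles compared
    against dose-matched energy-integrating and photon-counting fan-beam CT.
    Builds voxelised contrast-depth and mouse-like phantoms, transports a
    polychromatic pencil beam, forms energy-binned XFET count volumes with a
    single-scatter Compton background and slit-aperture geometry, simulates
    curved-detector fan-beam CT with Siddon raytracing, beam-hardening
    correction and short-scan filtered backprojection, and quantifies
    contrast-to-noise ratios, Rose-criterion detectability and depth-dependent
    gold detection limits.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'RcppExports.R'
    'accessors.R'
    'materials.R'
    'compton.R'
    'phantoms.R'
    'spectrum.R'
    'ct-simulator.R'
    'xfet-geometry.R'
    'xfet-simulator.R'
    'dose.R'
    'metrics.R'
    'xfet-imageformer.R'
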