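Package: stainkinetics
Title: Staining Kinetics of Heavy-Metal Contrast Agents from Time-Lapse
    X-Ray Projections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying and modelling the diffusion, binding and
    unmasking kinetics of osmium tetroxide staining in aldehyde-fixed tissue
    punches monitored by time-lapse X-ray projection imaging.  Provides a
    forward simulator of the coupled diffusion-reaction-advection equations
    for free, bound, available-site and masked-site densities on a curved-cap
    cylinder geometry; a preprocessing pipeline that turns projection stacks
    into standardized spatio-temporal absorbance profiles (registration,
    flat-field correction, cross-section extraction, baseline correction and
    intensity standardization); an inverse fit recovering the six kinetic and
    geometry parameters by bounded nonlinear least squares; staining-front
    detection with the square-root-of-time penetration law; binding-site
    stoichiometry accounting; and a synthetic-data generator that emulates
    the statistical structure of the raw recordings for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    tiff,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
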