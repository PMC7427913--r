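Package: skullray
Title: Ray-Based Phase Aberration Correction for Transcranial Focused
    Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for planning transcranial focused ultrasound (tcFUS)
    sonications through the intact skull.  Implements per-element ray
    tracing of a phased-array transducer through a CT skull volume
    (threshold-based collision detection with trilinear interpolation,
    Zucker-Hummel 3x3x3 surface-normal estimation, vector-form Snell
    refraction with critical-angle channel gating), Hounsfield-unit
    derived sound speeds, travel-time aberration-phase computation and
    per-channel correction-phase export, SVD-based rigid fiducial
    registration between transducer and CT coordinates, parametric
    synthetic skull phantoms with closed-form path-length oracles, and a
    monochromatic Rayleigh-summation forward model for in-silico
    validation of refocusing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    igraph,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
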