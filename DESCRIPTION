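Package: iplendo
Title: Iso-Pathlength Point Self-Calibration for Endoscopic Tissue Geometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for locating the iso-pathlength (IPL) point of diffuse
    reflectance in hollow-cylinder (endoscopic) tissue geometry and using it
    for self-calibrated absorption retrieval. Provides a curvature-corrected
    dual-source diffusion forward model of azimuthal and longitudinal full
    scattering profiles, a compiled Monte Carlo photon-transport simulator of
    a cylindrical air hole surrounded by scattering tissue
    (Henyey-Greenstein phase function), crossing-point estimation for
    families of scattering profiles, Beer-Lambert inversion of the
    differential pathlength factor and absorption coefficient at the IPL
    point, an endoscope-frame image-processing pipeline, and synthetic-data
    generators (frames, curve families, absorption workflows) with known
    ground truth.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    tiff,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
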