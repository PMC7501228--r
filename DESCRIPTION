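Package: gixtex
Title: Grazing-Incidence X-Ray Texture Analysis of Plant Cell-Wall Cellulose
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the crystal texture of cellulose in plant
    primary cell walls from grazing-incidence wide-angle X-ray scattering
    (GIWAXS), transmission WAXS and specular rocking scans. Provides
    closed-form X-ray optics (wavelength, electron density, critical angle,
    penetration depth), exact grazing-incidence mapping of area-detector
    frames to reciprocal-space (q, chi) coordinates with Ewald-curvature
    correction and missing-wedge masking, monoclinic unit-cell
    crystallography for cellulose I-beta with Scherrer size broadening,
    a forward renderer for synthetic detector frames and rocking series,
    sector/azimuthal/cake reduction with local background subtraction,
    chi-pole-figure assembly by stitching GIWAXS and rocking branches, and
    texture/crystallinity metrics (oriented fraction, distribution width,
    Segal crystallinity index).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
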