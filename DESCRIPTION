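Package: hypercine
Title: Motion-Compensated Chemometric Analysis of Hyperspectral Videos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing hyperspectral videos: radiometric calibration
    of intensity cubes against dark and white references, apparent-absorbance
    transformation, dense optical-flow motion estimation and back-morphing of
    every wavelength channel to a common reference geometry, extended
    multiplicative signal correction (EMSC) for separating pathlength, baseline
    and constituent-abundance variation, and a streaming self-expanding
    bilinear subspace model (on-the-fly processing) that discovers unknown
    systematic variation in the EMSC residual stream. Includes a ground-truthed
    synthetic hyperspectral-video generator emulating a shrinking, drying
    specimen, and an end-to-end pipeline producing temporal, spectral and
    spatial summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
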