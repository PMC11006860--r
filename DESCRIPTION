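Package: phaseseg
Title: Multiphase Phase-Field Image Segmentation with a Cubic Spline
    Transition Potential
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Segments single-channel raster images into K phases by
    minimizing a multiphase Mumford-Shah-type energy with an explicit
    Allen-Cahn gradient flow.  The phase transition potential is a
    periodic piecewise-cubic ("bi-cubic spline") multi-well function of
    the fractional part of the phase field, region fidelity is measured
    through sinc-squared weighted region means, and interface cells can
    be refined on a subgrid via bicubic interpolation through cell
    centers.  Includes seeded piecewise-constant phantom generators with
    ground-truth labels, contour and label-map extraction at half-integer
    level sets, and command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
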