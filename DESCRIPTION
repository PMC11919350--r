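Package: plenoscope
Title: Mirror-Scanned Light-Field Microscopy Reconstruction and Scan Planning
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Processing chain for light-field (plenoptic) microscopy augmented
    with a motorized tilting mirror in the Fourier plane of the detection
    module. Covers microlens-array grid calibration and rectification of raw
    sensor frames into 4D light fields I(x,y,u,v), perspective extraction and
    shift-and-sum synthetic refocusing, sub-microlens multi-frame
    super-resolution by pixel interleaving, phase-correlation mosaicking of
    tile scans into an extended field of view, adaptive region-of-interest
    scan planning, and USAF-1951 resolution metrology (tri-bar Michelson
    contrast, bead FWHM). A geometric-optics forward simulator generates raw
    frames from 3D phantoms (resolution targets, beads, shell-of-nuclei
    aggregates) so the whole chain is testable without a microscope.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
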