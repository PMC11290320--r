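Package: collimap
Title: Functional Visual Map, Dye-Coupling and Arrest-Behavior Analysis for
    the Superior Colliculus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for periodic-stimulation intrinsic optical
    imaging of the mouse superior colliculus and visual cortex: per-pixel
    Fourier demodulation of stimulus-locked movies, retinotopic and
    orientation preference map reconstruction with hemodynamic-delay
    correction, rigid cross-animal map registration, pixel-wise
    Moore-Rayleigh reproducibility testing, quantification of selective
    domains and visual-field coverage, spatial-geometry analysis of
    gap-junction dye-coupling networks, and flash-aligned locomotor arrest
    quantification from pose-tracking tables. Includes seeded synthetic-data
    generators with known ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    signal,
    zoo,
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
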