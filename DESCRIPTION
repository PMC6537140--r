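Package: flimhca
Title: High-Content Analysis of Time-Gated FLIM Plates for FRET Readout
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An automated analysis pipeline for wide-field time-gated
    fluorescence lifetime imaging (FLIM) of multiwell plates, aimed at
    reading out FRET between fluorescent-protein-labeled kinetochore
    proteins in budding yeast via the donor lifetime. Covers reading
    per-field-of-view gated image stacks with their gate-delay metadata,
    intensity integration and dead-cell exclusion, nonlinear top-hat
    detection of diffraction-limited kinetochore foci, hollow-square
    median subtraction of the local time-varying background, image-wise
    monoexponential lifetime fitting with reference-reconvolution
    handling of the instrument response function and of incomplete
    decays under high-repetition-rate excitation, total-signal quality
    control, and per-strain rank-sum statistics with Bonferroni
    correction. A synthetic gated-microscope simulator generates plates
    with known ground truth so that every stage of the chain is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    tiff,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
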