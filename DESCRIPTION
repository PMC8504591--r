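Package: slitfov
Title: X-Ray Field Boundary Measurement with a Fluorescent-Foil Slit Camera
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring how far a collimated radiographic X-ray field
    extends beyond the image detector by imaging, through a slit camera, the
    fluorescence X-rays emitted by a thin metal foil placed in the beam.
    Implements the slit-projection boundary formula and its inverse,
    edge localization on integrated line profiles by linear-fit extrapolation,
    an analytic depth-resolved fluorescence-signal model for optimizing the
    foil material and thickness under modelled tube spectra, compliance checks
    against mammography quality-control limits (MQSA/CFR 2% of SID, EU 5 mm),
    and a synthetic scene renderer with known ground truth for validating the
    full measurement pipeline without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
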