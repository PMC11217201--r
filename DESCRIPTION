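Package: flowphantom
Title: Flow-Phantom Simulation and Kinetic Analysis for Radiowater PET
    Perfusion Quality Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quality control of quantitative myocardial perfusion
    PET using a physical flow phantom and [15O]H2O. Provides a digital twin of
    the phantom experiment (injector bolus, well-mixed input chamber, exchange
    cylinder, radioactive decay, clinical 24-frame dynamic sampling and
    frame-dependent noise), the phantom-specific one-tissue compartment model
    with input-signal-fraction and delay terms, bounded weighted least-squares
    fitting that converts rate constants to flow values, and the accuracy,
    test-retest repeatability, Bland-Altman and flow-meter QC statistics used
    to compare PET/CT systems. Ships the measured study tables (two digital
    PET/CT systems, twelve pump/constriction settings, test and retest) so the
    published summary statistics can be recomputed offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
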