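Package: pdzavidity
Title: Bivalent Scaffold-Receptor Binding Kinetics and Membrane-Sheet
    Binding Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-action kinetic simulation of a homobivalent ligand (for
    example a PDZ-domain scaffold dimer such as PICK1) binding to pairs of
    identical membrane-embedded target sites, including the local-concentration
    rebinding step that gives rise to avidity.  Companion analysis tools cover
    the standard binding-assay fits: sigmoidal saturation and competition
    dose-response curves, mono-exponential association, one- and two-phase
    dissociation with AICc model comparison, fluorescence-polarization
    saturation and competition models, and quantification of two-channel
    membrane-sheet ROI intensities with labeling-degree, background and
    PMT-gain corrections and QC filtering.  A synthetic-data module generates
    every input class with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
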