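Package: picycle
Title: Kinetic Modelling of the Platelet Phosphoinositide Cycle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-action kinetic modelling of the phosphoinositide (PI) cycle
    downstream of Gq-coupled receptors, parameterised in molecule copy numbers
    per cell. Provides a declarative model container with three compartments,
    lipid-binding-protein buffering and time-triggered activation events;
    stiff ODE simulation with event handling (deSolve); steady-state analysis;
    log-grid parameter scans with a quantitative acceptance rule for
    calibration against time-course data; rescaling of a calibrated platelet
    model to other cell types via proteome copy numbers and compartment
    volumes; exhaustive mix-and-match scans of mosaic proteome datasets with a
    rule-based behaviour classifier; scaled finite-difference sensitivity of
    IP3 to initial protein levels; a seeded synthetic-data generator for time
    courses and proteome tables; and SBML Level 3 import/export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    yaml,
    xml2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
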