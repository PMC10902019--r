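Package: cowflow
Title: Flow-Conserving Circle-of-Willis Haemodynamics and Doppler Method Agreement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts extracranial duplex-ultrasound velocity envelopes into
    volumetric and mass inflow waveforms, distributes them across a
    Circle-of-Willis network using a seven-region outflow scheme with a
    Murray's-law per-outlet split, solves pulsatile flow through the network
    as a quasi-steady nonlinear Poiseuille circuit with Carreau-Yasuda blood
    rheology, extracts transcranial-Doppler-comparable middle-cerebral-artery
    velocity metrics, and compares simulated against measured velocities with
    paired tests, Pearson correlation and Bland-Altman agreement in absolute
    and relative-change terms. Includes a reproducible synthetic-cohort
    generator and grid-convergence-index arithmetic for mesh verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
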