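Package: nervoct
Title: Polarization-Sensitive OCT Analysis of Electrostimulated Peripheral Nerve
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for polarization-sensitive
    optical coherence tomography (PSOCT) studies of peripheral nerve
    electrostimulation injury. Generates ground-truth three-fascicle nerve
    phantoms and forward-simulates polarization-diverse tomograms; reconstructs
    the six PSOCT image channels (reflectance, attenuation, cumulative phase
    retardation, calibrated optic axis, degree of polarization uniformity and
    birefringence-weighted optic axis); computes decorrelation angiography with
    en-face vessel diameter and vessel-fraction metrics; extracts fascicle-level
    injury metrics with delta-versus-baseline group statistics; computes
    Shannon-model stimulation dosing, immunofluorescence pixel quantification
    and walking-track functional indices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tiff,
    jsonlite,
    mgcv,
    EBImage,
    emmeans
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
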