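Package: opmsim
Title: Simulation and Source Analysis for Triaxial OPM-MEG Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for simulating and analysing magnetoencephalography (MEG)
    recordings made with arrays of triaxial optically pumped magnetometers
    (OPMs). Provides forward models for current-dipole phantoms (Biot-Savart
    fields of a triangular coil) and neural sources (current dipole in a
    homogeneous conducting sphere), a sensor model covering open- and
    closed-loop operation including gain suppression and cross-axis
    projection error in background fields, synthetic session generators
    (visuo-motor paradigm, phantom linearity and background-field sweep
    protocols, a sitting-to-standing task), preprocessing (bad channel and
    trial rejection, notch and band-pass filtering, homogeneous field
    correction), scalar LCMV beamforming with pseudo-T and pseudo-Z
    volumetric imaging and virtual electrodes, Hilbert-envelope
    time-frequency spectrograms, and phantom linearity and error analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    RNifti
Config/testthat/edition: 3
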