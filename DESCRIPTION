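Package: seegvc
Title: Validation of EEG Volume-Conduction Head Models with Stereotactic EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess the accuracy of finite-element volume-conduction
    head models against intracranial (stereotactic EEG) recordings of
    electrical stimulation artifacts. Provides concentric-sphere head
    phantoms with 3-, 4- and 5-compartment conductivity profiles, an
    analytical multilayer-sphere dipole solver used as a numerical oracle,
    a geometry-adapted hexahedral finite-element forward solver with
    partial-integration dipole sources and point sensors, a synthetic sEEG
    recording generator for volume-conducted stimulation pulses, the
    measurement-side processing chain (filtering, epoching, channel
    exclusion, bipolar montage, peak extraction), and model-validation
    statistics: an L1-optimal amplitude scaling factor, absolute and
    relative error tables, cumulative error distributions, and
    distance-binned error summaries.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    signal,
    RNifti,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
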