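Package: eegfmri
Title: EEG-Informed fMRI Fusion and Resting-State BOLD Measures
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Scriptable analysis of simultaneous EEG-fMRI recordings:
    voxelwise resting-state measures (local/global/long-range functional
    connectivity density, spatio-temporal consistency of local BOLD
    activity, dynamic variability indices), nuisance-signal regression and
    ideal bandpass filtering of 4D BOLD series, EEG conditioning and
    feature extraction (re-referencing, zero-phase filtering, event
    management, band power, ERP amplitudes), hemodynamic response
    modelling, EEG-informed voxelwise general linear models including a
    multi-peak maximum-T variant, and local multimodal serial analysis
    fusing a lagged EEG feature matrix with the local BOLD neighbourhood
    through canonical correlation. Includes seeded synthetic-data
    generators for every input, readers and writers for NIfTI/Analyze
    volumes, motion-parameter text files, EDF and BrainVision EEG, and a
    command-line pipeline driver with provenance records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    signal,
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'io-volume.R'
    'io-eeg.R'
    'denoise.R'
    'fcd.R'
    'foca.R'
    'dynamics.R'
    'eeg-features.R'
    'hrf.R'
    'design.R'
    'glm.R'
    'lmsa.R'
    'simulate.R'
    'cli.R'
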