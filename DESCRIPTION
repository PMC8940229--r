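Package: ecogng
Title: Electrocorticographic Go/No-Go Motor-Inhibition Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for intracranial (ECoG) recordings acquired
    during Go/No-Go response-inhibition tasks: common-average rereferencing,
    line-noise notch filtering, high-gamma (70-200 Hz) Hilbert-envelope
    activation mapping and electrode selection, Morlet-wavelet event-related
    spectral perturbation, short-time Fourier band-power peaks and the
    No-Go/Go power ratio, theta-phase to high-gamma-amplitude coupling via
    the composite-signal modulation index with circular-shift permutation
    significance, and cross-patient condition comparisons with Tukey-Kramer
    correction plus rank-based age-trend statistics. Includes a synthetic
    cohort generator that injects known task-locked oscillatory structure
    (1/f background, line noise, cue-locked bursts, condition-dependent band
    gains, phase-amplitude coupling, and an age-dependent lateralization
    model) for validation and power simulation, and EDF/TSV session I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
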