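Package: PulseFlow
Title: Velocimetry of Physiological Brain Pulsations from Fast Volumetric MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the three-dimensional velocity (magnitude and
    direction) of cardiovascular, respiratory, and vasomotor brain
    pulsations from fast (10 Hz) volumetric MRI series. Implements dense
    and sparse 3D Lucas-Kanade optical flow with multi-resolution
    pyramids, physiological band separation (periodogram power maps,
    zero-phase band-pass filtering, aliasing arithmetic), pulse-cycle
    triggering and resampling with directional circular statistics, and
    group statistics (paired sign-flip permutation tests with
    threshold-free cluster enhancement, directional-reversal mapping,
    spatial power-velocity correlation, and log-power regression against
    slow-delta EEG power with Chebyshev outlier exclusion). Ships
    synthetic generators for a pulsatile porous-medium flow phantom with
    known ground-truth displacement and for awake/sleep cohorts, so the
    whole pipeline is testable end to end without any acquisition.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    pracma,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
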