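Package: wallmotion
Title: Temporospatial Characterization of Ventricular Wall Motion from
    Real-Time Cardiac MRI
Version: 0.1.0
Authors@R: person("Maintainer", "Package", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies left- and right-ventricular wall motion from
    ungated, free-breathing (real-time) short-axis cardiac MRI time series
    spanning several sequential heartbeats. Two temporospatial indices are
    computed from the complex image series: temporal periodicity, the
    fraction of spectral energy of a high-pass-filtered reference
    wall-motion signal concentrated at the cardiac frequency, and spatial
    coherence, the mean voxelwise Pearson correlation between the reference
    signal and every time series inside the ventricular anatomy. Includes a
    synthetic beating-heart phantom with ground truth, method-of-slices
    volumetrics (EDV, ESV, SV, EF), SNR/CNR image-quality metrics, a group
    statistics layer (Anderson-Darling normality, one-tailed Welch t,
    index cross-correlation), minimal NIfTI-1 input/output and a command
    line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
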