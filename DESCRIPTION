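Package: smsfus
Title: Simultaneous Multi-Slice Functional Ultrasound Processing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing pipeline for simultaneous multi-slice functional
    ultrasound (fUS) neuroimaging with a motorized multi-array probe. Covers
    acquisition scheduling and volume timing, plane-wave delay-and-sum
    beamforming on a trapezoidal grid with coherent compounding, SVD clutter
    filtering of IQ blocks and Power Doppler image formation, slice-timing
    correction, detrending, calm-period detection, band-pass filtering and
    global-signal regression, task-activation GLM statistics with Bonferroni
    and TFCE max-statistic permutation inference, resting-state functional
    connectivity (seed maps, Fisher-averaged correlation matrices, FDR),
    icasso-stabilized spatial ICA, and quality-control metrics (CNR, matching
    score, calm score). Includes a synthetic-data generator producing IQ
    phantoms and 4D Power Doppler series with planted hemodynamic responses,
    network covariance, drift and motion episodes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
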