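---
title: "Methods: multi-slice functional ultrasound processing in smsfus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-slice functional ultrasound processing in smsfus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smsfus)
```

# Overview

`smsfus` implements the computational chain of simultaneous multi-slice
functional ultrasound (fUS) neuroimaging with a motorized multi-array probe:
acquisition scheduling, plane-wave beamforming, SVD clutter filtering and
Power Doppler (PD) formation, resting-state/task preprocessing, GLM
activation statistics with familywise-error control, functional-connectivity
analysis, and stabilized spatial ICA. A synthetic-data generator produces
every input the pipeline needs at desk scale, so the entire chain is testable
without animal data.

This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic tests do — and do not
— establish about real data.

# Acquisition model

## Probe and schedule

The probe model (`probe_geometry()`) is four compact linear arrays of 64
elements at 110 µm pitch, arrays spaced 2.1 mm apart, each focused in
elevation to a ~0.5 mm slice by an acoustic lens; 256 channels total. One
volume is acquired by stepping a motor through `n_positions` positions
spaced `inter_array_mm / n_positions` apart, so the four slices per position
tile the elevation axis contiguously. The volume repetition time is

$$\mathrm{TR} = n_\mathrm{pos}\,(T_\mathrm{int} + T_\mathrm{trans}),$$

with defaults $n_\mathrm{pos} = 4$, $T_\mathrm{int} = 0.4$ s,
$T_\mathrm{trans} = 0.2$ s, giving TR = 2.4 s and 16 slices at 0.525 mm.
$T_\mathrm{trans}$ is modeled as a constant dead time regardless of distance:
the motor bound is what defines the schedule, and it is configurable.

Positions are visited in an interleaved order — 1-3-4-2 for four positions —
which caps the largest move, including the wrap from the last position back
to the first, at two steps (1.050 mm); a sequential order would wrap across
three. For other position counts the generalized rule visits odd-indexed
positions in ascending order and then even-indexed ones; the four-position
order is pinned to 1-3-4-2 (the generalized rule alone would give 1-3-2-4,
which has a poorer wrap). Each slice records the onset time of its position
within the TR; these offsets drive both the simulator and slice-timing
correction.

Elevation coordinates are Bregma-relative millimeters, anterior positive,
slice 1 most anterior. With default settings the 16 slices span 7.875 mm
(15 × 0.525 mm); we report exact arithmetic rather than rounded field-of-view
endpoints.

## Beamforming

Frames are formed per array by delay-and-sum (`das_beamform()`) over tilted
plane-wave transmissions (default 8 angles evenly spaced in ±12°, PRF 4 kHz,
hence 500 Hz compound rate), coherently averaged by `compound()`. The
reconstruction grid (`trapezoidal_grid()`) widens laterally with depth at
$\tan\theta_\mathrm{max}$, recovering regions beyond the 64-element aperture.
The per-voxel delay is

$$\tau(x, z) = \frac{z\cos\theta + x\sin\theta}{c} +
  \frac{\sqrt{z^2 + (x - x_e)^2}}{c}.$$

Unspecified implementation details are declared configuration: linear-in-time
interpolation of the IQ samples, rectangular receive apodization within an
f-number acceptance cone (default f-number 1.0; `Inf` accepts all elements),
no transmit apodization. Delays falling outside the recorded samples
contribute zero. Channel data are assumed complex baseband; the synthetic
channel model (`simulate_channels()`) emits analytic echo pulses with a
configurable carrier, since it is the carrier phase that makes focusing and
angle compounding interfere correctly. Each array is beamformed on its own
grid; there is no cross-array coherent summation.

# Clutter filtering and Power Doppler

A 0.4 s block of 200 compound frames is reshaped to a Casorati matrix
(voxels × time; R-native column-major voxel order, `casorati()`), decomposed
by SVD, and the blood signal is the residual after removing the first
$N_\mathrm{cut}$ spatiotemporal modes:

$$S_\mathrm{blood} = \sum_{i > N_\mathrm{cut}} U_i\,\lambda_i\,V_i^{*}.$$

The PD image is the temporal mean of $|S_\mathrm{blood}|^2$ per voxel. The
split conserves energy exactly (orthogonal modes), which the tests assert to
1e-10.

For motion-free (anesthetized) data the fixed default is $N_\mathrm{cut}$ =
60. For awake data with episodic motion, `adaptive_ncut()` picks the smallest
$n$ whose leading modes hold a fixed fraction of the total energy
$\sum\lambda_i^2$ (default 0.95, configurable), with at least one mode always
removed. Two choices here were genuinely open and are documented as such:
the adaptive rule operates on cumulative *energy* ($\lambda^2$), not
amplitude, and the SVD is computed on the raw matrix without mean removal —
a static tissue mean is itself captured by mode 1, so removal would be
redundant. The Casorati support is the whole slice (no sub-block tiling).

# Synthetic data

The generator is the package's statement of the study conditions, not a
tunable fixture.

`make_iq_phantom()` builds IQ blocks from three components: up to three
high-energy tissue modes (unit-magnitude near-orthogonal phase patterns ×
slow sinusoidal phase modulation, one motion harmonic per mode, so each
planted mode is a distinct spatiotemporal SVD mode of exactly rank one);
blood as fast-decorrelating per-voxel complex speckle on a Doppler phase ramp
confined to a vessel mask (fast decorrelation is what spreads blood energy
across many temporal modes, as in real flow); and circular white complex
noise. Defaults put tissue 40 dB above blood (amplitudes 100 vs 1).

`simulate_pd_series()` builds 4D PD series: per-region latent signals drawn
from a network covariance and band-limited to 0.01–0.1 Hz, using the *same*
Butterworth band-pass design as the preprocessing module so the generative
band matches the analysis band; HRF-convolved boxcar responses scaled to a
stated % of baseline in chosen regions; degree-3 polynomial drift; episodic
multiplicative global-signal excursions standing in for motion (spatial
displacement and registration are out of scope); and white voxel noise.
The baseline PD level is 100 arbitrary units so % rCBV reads directly.
Latents are generated on a fine grid and each slice samples them at its true
within-TR onset, so slice-timing correction is testable end to end. The
realized latent series are empirically whitened before mixing, so the sample
correlation of a noiseless simulation equals the requested covariance rather
than fluctuating with the few effective degrees of freedom of band-limited
noise. All generators are deterministic given their seed and echo their
parameters as provenance.

The stimulus model (`make_stimulus()`) is the block visual protocol: 60 s
baseline, then 8 stimuli of 30 s repeated every 90 s — 780 s total, 325
volumes at TR 2.4 s.

What the phantom does *not* emulate: realistic vasculature and neurovascular
coupling, spatially correlated noise, probe/tissue motion as displacement,
aberration. Passing tests establish internal consistency and statistical
calibration of the chain, not in-vivo validity.

# Preprocessing

The pipeline order is fixed: slice-timing correction → degree-3 polynomial
detrending → calm-period detection → per-segment standardize + band-pass →
concatenation → global-signal regression (GSR). GSR and the calm/band-pass
stages apply to the awake resting-state configuration; anesthetized task data
uses slice-timing correction and detrending only.

* **Slice-timing correction** resamples each slice onto the first position's
  time base by linear interpolation; endpoints are edge-held. Linear signals
  are recovered exactly.
* **Calm periods**: the global signal (GS) baseline is a linear regression
  over the scan; volumes whose rolling standard deviation (window 24 s ≈ 10
  volumes, configurable — long enough to estimate a variance, short against
  the 60 s minimum) stays below 5% of the *local* baseline value are calm,
  and maximal calm runs of at least 60 s are kept. The calm score is the
  retained duration; scans under 600 s of calm are flagged excluded. The
  threshold is relative, so detection is invariant to affine rescaling of
  the GS. Calm detection uses the GS of the raw (pre-detrend) series, with
  its own independent baseline estimate.
* **Band-pass** is a 4th-order Butterworth, 0.01–0.1 Hz, applied
  forward-backward (zero phase, effective order 8) — the standard
  resting-state choice. Each calm segment is z-scored per voxel *before*
  filtering and the filtered segments are concatenated; the
  standardize-then-filter order is deliberate.
* **GSR** projects the brain-mean time course (plus intercept) out of every
  voxel by least squares. The tests reproduce its known artifact: truly
  uncorrelated voxel pairs acquire negative correlation after GSR.

# Activation statistics

The stimulus regressor is the boxcar convolved with a four half-cosine
canonical HRF and rescaled to 0 at rest / 1 during sustained stimulation.
The rescaling contract constrains amplitude, not shape, so the four segment
durations are configuration: onset delay 0.5 s, rise 1.0 s, fall 3.0 s,
recovery 3.5 s (~8 s kernel, undershoot disabled, peak 1) — a conventional
shape for rodent CBV responses.

`glm_fit()` is ordinary least squares per voxel with a contrast t-statistic,
two-sided Student p-values, and the intercept as the modeled baseline; rCBV
is $100\,(y - \mathrm{baseline})/\mathrm{baseline}$. Subject-level maps are
Bonferroni-corrected at FWER 0.05 over in-mask voxels. Serial autocorrelation
of the PD series is not modeled (no prewhitening); the Monte-Carlo
calibration tests quantify the realized type-I error under white noise, and
this is a known limitation for strongly autocorrelated real data.

Group inference is a one-sample t-test across subject t-maps with
threshold-free cluster enhancement (E = 0.5, H = 2, dh = max/100,
6-connectivity — the standard published defaults) and max-statistic
sign-flipping permutations: exhaustive when subjects ≤ 12 (all $2^n$ flips),
random otherwise. A voxel is significant when its FWER-corrected permutation
p-value (fraction of the max-null at or above the observed enhancement) is
≤ α; rejecting on the p-value rather than the threshold quantile keeps the
test valid under the discreteness of exhaustive sign-flipping. Two-tailed by
default; seed maps use the one-tailed variant.

# Connectivity and ICA

Region time series are voxel means within an integer label volume; empty
regions are reported absent, never zero-filled. FC matrices are pairwise
Pearson correlations (exact symmetry enforced; undefined entries from
constant series are masked, not imputed). Group averaging is Fisher z →
arithmetic mean → back-transform, with off-diagonal |r| = 1 clipped at
1 − 1e-7 under a warning. Group significance is a per-entry one-sample
t-test on Fisher z with Benjamini-Hochberg correction over the upper
triangle only (entries are duplicated by symmetry). The specificity QC
metric reports the correlation between homotopic somatosensory regions
(specific) and between somatosensory and anterior cingulate cortex
(unspecific); region names are configurable because toy label sets differ
from an atlas segmentation.

Spatial ICA (`run_ica()`) whitens to the requested dimensionality by PCA and
runs symmetric fixed-point iteration with the log-cosh contrast; components
are spatial maps (voxels as samples), deterministic given the seed, with a
deterministic sign convention. Contrast and whitening details are
configuration since several choices are defensible. Stabilization
(`icasso_cluster()`) pools components from repeated randomized runs
(production default 100 runs; desk-scale analyses and tests use 20),
measures similarity as |Pearson correlation| of maps (sign-invariant),
clusters by average linkage into as many clusters as the dimensionality
(the icasso convention — the cluster count is not estimated), and reports
each cluster's centrotype and stability index Iq = mean intra-cluster −
mean extra-cluster similarity. Candidate dimensionalities follow the field:
15, 25, 35. Maps are Z-scored over in-brain voxels and thresholded at
|Z| > 3; for a standard-normal map this masks $2\Phi(-3) \approx 0.27\%$ of
voxels (the two-sided tail is 0.0027, not 0.001; the package reports exact
tail values and leaves the threshold at 3). Components are ranked and
accompanied by region-overlap tables; classifying components into named
networks remains a human decision.

# Numerical choices and degenerate inputs

* Zero-variance voxels: z-scoring substitutes unit variance (leaving zeros);
  constant FC series are masked; constant seeds and constant maps are errors.
* `svd_filter(n_cut = 0)` returns its input unchanged; `n_cut ≥ n_frames`
  is an error.
* TFCE integrates from `dh` upward; maps whose maximum is below one step
  enhance to zero. Enhancement of negative values uses the negated map, and
  the two tails are recombined with sign.
* Permutation p-values are bounded below by 1/(number of permutations).
* Beamforming voxels outside the trapezoid are `NA`, not zero; delays beyond
  the recording contribute zero.

# Problem sizes

Test and acceptance runs use desk-scale sizes chosen to exercise every code
path with tight statistical bounds: 32×32×200 IQ phantoms; 6×4×2 to 12×12×2
label volumes; 500-volume resting scans; 500-replicate Monte-Carlo
calibrations for type-I error, FWER and FDR; 20 ICA runs for stabilization;
exhaustive sign-flipping for ≤ 12 subjects. The full suite runs in well
under a minute per module.

# Known limitations

* No prewhitening for serial autocorrelation in the GLM.
* Motion is modeled as global-signal excursions; registration-based motion
  correction and atlas registration itself are out of scope (only the
  matching-score metric is provided).
* The beamformer is 2D in-plane; elevation focusing is fixed by the lens
  model and not simulated.
* Velocity estimation, IIR wall filters and sub-block SVD variants are not
  implemented.
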