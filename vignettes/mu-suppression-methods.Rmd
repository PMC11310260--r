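---
title: "Methods: mu-suppression analysis, source inversion and neurofeedback calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mu-suppression analysis, source inversion and neurofeedback calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musuppr)
```

## The scientific problem

The sensorimotor mu rhythm (8–13 Hz over central electrodes) is attenuated
both when a person performs an action and when they watch someone else
perform it, which makes mu suppression a candidate EEG biomarker of the
human mirror-neuron system. Studies in this area compare mu-band power while
participants watch biological-action videos (simple hand movements,
goal-directed hand movements, social interactions) against a
non-biological-motion baseline (moving balls), before and after a
neurofeedback intervention that trains participants to suppress mu.

`musuppr` implements that analysis chain end to end — preprocessing, Welch
spectra, the Mu Suppression Index with its inferential battery, a weighted
minimum-norm source estimate with cluster-based sign-flip permutation
contrasts, and the threshold neurofeedback protocol — together with a
forward-model synthetic EEG generator, so every stage can be validated
against a known ground truth without access to raw recordings.

## The statistic: Mu Suppression Index

For each subject, session, condition and location,

$$\mathrm{MSI} = \log_{10}
  \frac{P_\mu(\text{condition})}{P_\mu(\text{baseline})},$$

where $P_\mu$ is the mean power spectral density over 8–13 Hz (inclusive
band edges; 11 bins at the 0.5-Hz resolution of 2-s windows). The ratio
cancels subject-specific scale factors (scalp thickness, impedance); the log
makes the statistic symmetric around zero. Negative values indicate
suppression. Because power scales with the square of amplitude, a source
whose amplitude is multiplied by a gain $a$ in one condition has a true MSI
of exactly $2\log_{10}a$ — the identity the synthetic generator's ground
truth is built on, and the basis of the recovery benchmarks.

## The synthetic world

`simulate_study()` emulates the standard design: 16 subjects, two sessions
(`pre`, `post`), four video conditions of five 24-s clips each, two 120-s
resting blocks, 64 channels at 512 Hz. Deviations from a real study, and the
reasons for each modelling choice:

* **Head geometry.** Sources sit on a quasi-uniform upper hemisphere at 80%
  of the electrode-shell radius; the lead field is the classical closed-form
  potential of a radial dipole in a homogeneous conducting sphere. This
  replaces a boundary-element model on a template anatomy: it needs no
  anatomical data and preserves exactly the property the inverse stage
  depends on — smooth, distance-dependent spatial mixing. Electrode
  positions are idealized 10-10 coordinates generated procedurally
  (synthetic, not digitized).
* **Source waveforms** are band-limited Gaussian noise (FFT brick-wall into
  the band, unit RMS), not sinusoids: real mu is not phase-locked, and
  broadband waveforms actually exercise Welch averaging.
* **Background** is per-channel $1/f$ noise (unit RMS, exponent 1) plus
  white sensor noise (unit SD). The study this emulates reports no absolute
  power scales, so only ratios are anchored: source base amplitudes are free
  parameters, chosen once so that the mu source's band SNR at its nearest
  channel is of order 100 — clean but not noise-free, comparable to a good
  recording at C3. They are not tuned per experiment.
* **Subject variability** is a log-normal amplitude jitter (sdlog 0.2) drawn
  once per subject. It multiplies all sources equally, so it cancels in the
  MSI ratio but makes absolute powers — and hence the ANOVA error strata —
  realistically heterogeneous.
* **The occipital alpha confound** is an ordinary source (8–13 Hz, posterior
  vertex, 1.5× the mu amplitude), reproducing the concern that posterior
  alpha leaks into C3/Cz/C4. It is present in the default source layout so
  sensor-space tests run against a world where the confound exists.
* **Not modelled:** eye blinks and movement artifacts (the artifact-removal
  steps of the original pipeline are out of scope), realistic anatomy,
  inter-channel impedance differences, and any learning dynamics across
  neurofeedback sessions.

A green simulation test therefore establishes that the *statistical
machinery* is correct under a fair forward model — not that the pipeline is
robust to artifacts or anatomical error.

## Preprocessing and spectra

Processing order is DC removal → average reference → per-clip edge trimming
→ concatenation. The two de-meaning steps commute, so their order is
immaterial; trimming last keeps clip bookkeeping simple. Trims are 2 s per
action clip and 10 s per resting block (posterior alpha is sensitive to clip
transitions), giving the canonical 100-s analysis segment in both cases.
Every clip is trimmed at both ends — the stricter reading of the block
design, consistent with "five 20-s epochs per condition". Trim seconds are
converted to samples by rounding to the nearest sample.

Welch PSD uses 2-s Hamming windows at 50% overlap, arithmetic averaging, no
detrending beyond the upstream DC removal, and no zero padding. The
normalization convention (not stated in the source material) is the
one-sided *density* convention: window power is divided by `fs * sum(w^2)`
and doubled off DC/Nyquist, so the PSD integral approximates signal
variance. That choice makes Parseval checks exact test oracles: a
unit-amplitude on-bin sinusoid integrates to 0.5 over its band, unit
variance white noise integrates to 1.0.

## Sensor-space inference

`msi_ttest_zero()` is the one-sample t-test (df = n − 1) with Cohen's
d = mean/sd and the t-based CI. `rm_anova()` handles balanced fully-crossed
within-subject designs of any order via the classical inclusion–exclusion
identity over marginal totals, testing each effect against its interaction
with subjects; it is validated against `stats::aov` Error-stratum output to
1e-8. Greenhouse–Geisser epsilon is estimated from the covariance of the
orthonormalized effect contrasts (Kronecker products across the factors of
an interaction), clamped to `[1/df, 1]`; Mauchly's test is reported as a
diagnostic flag but never gates the correction — the corrected p-value is
always available. One quirk of the emulated report is handled explicitly:
with 16 subjects a one-sample test has df = 15, and the package always
reports df = n − 1.

The median split into "suppressers"/"non-suppressers" is order-based: stable
ascending sort of first-session MSI, lower half (strongest suppression) =
suppressers. For even n without ties this equals "strictly below the
median", and it keeps group sizes equal under ties by construction.

## Source inversion

The inverse is a weighted minimum-norm kernel
$K = W L^\top (L W L^\top + \lambda^2 I)^{-1}$ with identity noise
covariance — the appropriate choice when trials are few and the baseline is
non-conventional — and diagonal depth weights
$w_v = \lVert L_{\cdot v}\rVert^{-2\gamma}$. The regularization and depth
parameters are not reconstructions of any published values (the original
analysis delegates them to its toolbox); they are declared defaults:
$\gamma = 0.5$ (conventional depth compensation) and
$\lambda^2 = \mathrm{tr}(LWL^\top)/(N_{ch}\,\mathrm{SNR}^2)$ with SNR = 3,
the standard minimum-norm convention. Source orientation is fixed (radial),
matching the scalar synthetic lead field. Projection is linear, so PSD, band
power and MSI apply to vertex time courses unchanged, and scaling a
condition's channel data by $k$ shifts every vertex MSI by $2\log_{10}k$ —
a property used as a test invariant.

## Cluster-based sign-flip permutation

Per-vertex paired t-statistics (session B − A differences) are thresholded
at the two-tailed critical value at the cluster-forming alpha (df = 15 gives
|t| > 2.131); supra-threshold vertices form maximal connected same-sign
components under the mesh adjacency, each scored by its signed t-sum.
Design decisions where the prose being emulated is ambiguous:

* "Permuting contrasts between conditions" in a paired before/after design
  is implemented as per-subject sign flipping — the exact
  exchangeability-preserving relabeling for paired contrasts.
* The null stores **one signed extreme** (largest |sum|, sign kept; 0 when
  no cluster forms) per repetition, and observed clusters are tested against
  the 2.5th/97.5th percentiles of that single distribution. The alternative
  reading (separate positive and negative extremes) is not adopted; the
  single-distribution reading matches the description of one permutation
  distribution with two-sided percentile cut-offs.
* Per-cluster p is the two-sided exceedance proportion with the observed
  statistic included in the null (+1 correction), so p ≥ 1/(n_perm+1) and
  the test is valid at finite n_perm.
* A zero-variance vertex gets t = 0 (and a warning on observed data):
  it keeps pure-noise calibration simulations well defined.

Family-wise error calibration is verified empirically: on 200 pure-noise
datasets (16 subjects × 40 vertices) the fraction with any significant
cluster must sit inside the 95% binomial interval around 0.05, and with
n = 8 subjects Monte-Carlo p-values are checked against the exhaustive
$2^8$ enumeration.

## Neurofeedback protocol

The trained signal is the C3+C4 montage sum; the four trained bands are
theta 4–7, mu 8–13, beta 14–30 and high beta 20–40 Hz. The device's internal
amplitude algorithm is unpublished, so a standard estimator is declared:
zero-phase band-pass followed by a 0.25-s sliding RMS × √2 (a steady
sinusoid of amplitude A reads as A). Success requires **all** bands strictly
below threshold for at least 1 s contiguously; "below" is strict, an
arbitrary but fixed convention with measure-zero ties on continuous data.

Threshold calibration couples the four bands through a single common
quantile of each band's baseline amplitude distribution — the protocol
states one success range, not per-band targets, and one degree of freedom
makes the inverse problem well-posed. The quantile is found by bisection
(success fraction is monotone in every threshold, hence in the common
quantile) until the baseline success fraction lands in the target range
(75–80% early sessions, 65–75% late); degenerate amplitude distributions
raise a calibration failure rather than returning a boundary value.

## Numerical and interface conventions

* Times are in seconds; R-side sample indices are 1-based inclusive, file
  formats document their own conventions.
* The internal `.eegc` container stores float64 and round-trips
  bit-exactly; EDF export is 16-bit and lossy by format, with quantization
  bounded by half a step of the printed physical range (the writer quantizes
  against the *printed* 8-character limits so reader and writer share one
  linear mapping).
* A single pipeline seed fans out to per-stage seeds through a fixed
  integer-hash splitting rule (`split_seed`), making each stage individually
  reproducible.
* Meshes are triangulated by brute-force spherical Delaunay via
  stereographic projection — adequate for the desk-scale meshes (tens to a
  few hundred vertices) this package targets.

## Known limitations

* The spherical forward model has no skull/scalp conductivity layering;
  absolute source amplitudes are meaningless, only ratios matter.
* `rm_anova()` requires complete balanced designs; there is no mixed-model
  fallback for missing cells.
* The brute-force mesh triangulation scales as the cube of the vertex
  count; it is not intended for dense cortical meshes.
* Expensive acceptance benchmarks run in documented scaled-down worlds
  (fewer channels, shorter blocks, lower sampling rate) when the property
  they measure — e.g. a null rejection rate — is invariant to those scales;
  see `?bench_null_ttest_rate`.
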