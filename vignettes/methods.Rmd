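---
title: "Extracting subcellular membrane-potential signals at low SNR: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting subcellular membrane-potential signals at low SNR: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metroidr)
```

## The problem

Voltage-sensitive dyes report membrane potential as a small fractional
change in fluorescence (often below 10 % per 100 mV), so a time course
averaged over a small region of interest (ROI) of an isolated cell can sit
well below the shot-noise floor.  Classic remedies — temporal averaging over
repeated trials, or low-pass filtering — either cost experiments that
cannot be repeated (electroporation kills or remodels the cell) or distort
waveforms whose frequency content is unknown.  `metroidr` implements the
METROID strategy: treat the mean traces of many standardized ROIs as
parallel observations of one underlying cellular event mixed with
independent noise, and unmix them with blind source separation (BSS).

The pipeline is: cell mask → equal-area ROI segmentation (MESS) → per-ROI
photobleaching removal by non-linear curve fitting → PCA or ICA
decomposition of the ROI traces → selection of the signal source(s) →
inverse transformation (optionally with wavelet hard-thresholding of the
selected source) → baseline centering → per-ROI SNR estimation and, for
electroporation data, calibration to millivolts.

## MESS segmentation

A binary cell mask (auto-generated by Otsu thresholding of the
temporal-mean frame, closed, hole-filled, largest component kept) is
rotated so its principal axis is vertical, estimated from central second
moments; a disk, whose orientation is undefined, gets angle 0 by
convention.  Sequential 3×3 (8-connected) erosions shrink the mask until
the inner area first drops to at most `n_in / (n_in + n_out)` of the
total; the erosion count `n` defines the inner contour, and `floor(n/2)`
erosions define a mid contour strictly between the outer and inner ones.

The outer band is divided by arc-length: the mid contour is cut into
`n_out` equal-length segments starting from the point at the vertical
middle of the mask on its right side, traversed counter-clockwise on
screen (y pointing down).  Every band pixel then joins the ROI of its
nearest mid-contour segment.  We chose this nearest-arc assignment over
rasterizing straight cuts between closest outer/inner contour points: the
two coincide for convex shapes, but nearest-arc assignment partitions the
band exactly by construction and cannot produce self-intersecting sector
boundaries on concave cells.  The inner region is divided top-to-bottom by
area: one top ROI and one bottom ROI are reserved first (cell poles carry
the largest electroporation amplitudes), and the remaining central area is
halved by a vertical line, each half-column swept into `(n_in - 2)/2`
equal-area ROIs.  Outer ROIs are renumbered cyclically so ROI 1 sits at
the top of the aligned cell; we anchor the renumbering on the arc position
of the mid-contour apex rather than on segment centroids, because for a
symmetric cell two segments straddle the apex and a centroid rule flips
between them under the one-pixel jitter that rotation introduces.
Rotating labels back to the original orientation uses nearest-neighbor
lookup; pixels left unlabeled by rounding are assigned to the nearest
labeled neighbor inside the mask, so the partition of the mask is always
exact.

Equal areas are approximate by design: one erosion step quantizes the
inner/outer split (expect the inner fraction within ~0.06 of its target on
a typical cell-sized ellipse), and area equality degrades on strongly
non-convex shapes (neurites), which the method does not attempt to handle.

## Source signals and noise

Simulations use two source signals on a 5 s record with onset at 2.5 s:
an action-potential-like transient (active until 2.8 s) and a persistent
step (active to the end).  Shot noise is modeled as Poisson(λ = 225)
counts minus λ — zero mean, variance 225, nearly Gaussian (skewness
1/15).  SNR uses the classical power form, `mean(x_i^2) / σ²`, with the
mean over the *full* record (active plus silence); scaling signals, not
noise, sets the target SNR.

The AP surrogate is a two-frame upstroke to a peak of −1 (fluorescence is
inverted) followed by a biexponential repolarization whose two time
constants and mixing weight are solved numerically so the waveform crosses
25 % and 75 % repolarization at the requested APD₂₅/APD₇₅ (defaults 35 and
120 ms, a short ventricular AP at 100 frames/s).  The reference
implementation drew this signal from the Mahajan rabbit ventricular cell
model; a surrogate preserves the skewed unimodal amplitude distribution
and the time scales that BSS separation depends on, but its peak is a
sharp vertex rather than the model's broad spike-and-dome.  One measurable
consequence, discussed under *Limitations*: a 10 Hz low-pass Butterworth
attenuates this surrogate's peak by roughly 28 % regardless of noise,
where a plateau-shaped AP loses under 10 %.  A convex biexponential decay
cannot produce a plateau (it would need an accelerating early decay), so
this is an inherent property of the surrogate family, not a tuning issue.

Per-observation photobleaching contamination draws `A exp(-B t) + C` with
`A ~ N(2σ, (0.4 σ)²)`, `B ~ N(0.3 /s, 0.05²)`, `C ~ N(0, σ²/4)` (A, B
truncated positive): drift comparable to the noise scale, so correction is
non-trivial.  All randomness derives per-observation seeds from one master
seed; a dataset is fully determined by `(seed, n)`.

## Photobleaching correction

Four decaying models are supported: `exp` (`A e^{-Bt} + C`), `exp_step`
(adds `-E·u(t - t_onset)`), `exp_lin` (adds `-D t`) and `exp_lin_step`.
The step term represents the persistent *signal* so the whole record can
be fitted; the curve actually subtracted never includes it.  Three input
windows: **SBPC** uses only data before onset, **DBPC** all silence
intervals (transitory signals), **FDPC** the whole record with a
step-bearing model (persistent signals with known onset).  SBPC and DBPC
exclude the two frames straddling onset; FDPC excludes a 0.05 s guard
after onset, where charging transients that the step term cannot
represent would otherwise bias the fit.  Real-data-style corrections use
the `exp_lin*` models (the linear term absorbs the slow tail of
double-exponential bleaching); double exponentials are used only on the
simulation side, never for correction, because they converge unreliably.

Fitting exploits the model structure: `B` is the only non-linear
parameter, so it is profiled on a 60-point log grid with the linear
parameters solved by least squares at each `B`, and the grid optimum
seeds a Levenberg–Marquardt polish (`B` bounded to `[0, 50] /s`, up to 5
jittered restarts).  A single data-driven start proved unreliable at
−10 dB: the optimizer settled in local optima that overestimate the step
amplitude by ~10 % on average; the profiled start is the global optimum
of the profiled objective and removes that bias while leaving noiseless
parameter recovery exact to 10⁻⁶.

## BSS filtering

Traces are mean-centered; PCA comes from the SVD, and ICA whitens to `m`
principal components before a fixed-point FastICA (logcosh contrast,
deflation, tolerance 10⁻⁶, ≤ 1000 iterations, seeded initial rotation —
identical inputs and seed give identical outputs; non-convergence warns
and keeps the best iterate).  Automatic selection picks the source with
the most energy inside the active interval, computed on variance
normalized sources (raw energy would always pick the first principal
component); ties go to the lowest index.  Reconstruction multiplies only
the selected sources back through the mixing matrix and restores the
offsets, which makes the output invariant to ICA's sign/scale ambiguity.
Defaults follow the transitory/persistent distinction: ICA with the
discrete Meyer wavelet for APs, PCA with Haar for steps.

For `wPCA`/`wICA` the selected source passes through a decimated DWT with
hard threshold `K = sqrt(2 ln N)·σ`, where `N` and `σ` are the sample
count and the (unscaled) median absolute deviation of the finest detail
level; the single `K` is applied to all detail levels (configurable to
finest-only), approximation coefficients are never touched.  The
transform reflection-pads to the next power of two and runs a periodized
orthogonal pyramid, the inverse truncating to the original length —
reconstruction is exact to machine precision for Haar, and to the ~1 %
inherent to the standard 62-tap FIR approximation of the Meyer filter.

## Artificial videos

`compose_video()` builds `F = BF + g⊙Signal + Bleach(BF, t) + Noise`:
a smooth basal-fluorescence image `BF` (for real input frames,
`estimate_bf()` Gaussian-filters the first frame with a kernel as large
as the smaller image dimension and rescales to the grand mean); a
membrane-potential signal modulated by `BF`; double-exponential
photobleaching (defaults 3 % and 1 % of `BF` at 0.05 and 0.5 /s — the
reference work calibrated these on recordings we do not have, so the
values are package choices of realistic magnitude); and per-pixel
independent zero-mean Poisson noise.  A per-ROI gain matrix `g` scales
the pure signal so every MESS ROI reaches its target SNR (realized within
±0.5 dB).  Negative composed intensities are clipped at zero with a
count recorded.  The electroporation signal uses the steady-state induced
transmembrane potential of a prolate spheroid in a uniform field
(Klee–Plonsey): `ΔV = E·u/(1 − L_a)` along the major axis with
depolarizing factor `L_a = (1−e²)/e³·(atanh e − e)` (and the analogous
transverse term), verified against the spherical limit `1.5·E·a`.  After
the pulse the charged membrane `(V_rest + ΔV)` relaxes toward 0 mV with
τ = 16.7 ms, so the deviation falls to ~5 % within 50 ms, consistent
with reported pore-formation dynamics; the pre-pulse baseline is
subtracted before `BF` modulation so the Eq.-style signal term is zero
during silence.  Blank videos for the subtraction baselines share the
bleaching but not the signal, and are rescaled so their global mean
exceeds the stimulated video's pre-onset mean by exactly the configured
0.3 %.

The simulator's defaults — 61×121 px elliptical cell, 100 frames/s, 5 s,
λ = 225 everywhere, −10 dB targets, 16 + 16 ROIs — are the desk-scale
study conditions used throughout the tests.  100 frames/s sits at the
upper end of the 50–100 frames/s experimental range; at 50 frames/s the
default APD₂₅ would be shorter than the two-frame upstroke and the AP
surrogate is rejected as infeasible.

## Evaluation and calibration

`trace_metrics()` reports the relative maximal-amplitude error
`E_r_Amp = (Amp_meas − Amp_true)/Amp_true` (positive = overestimate),
Pearson `r` over the active interval, RMSE, the relative error at the
true peak instant, and the relative error of the post-onset median
(stationary level).  Whole-cell timing detection places the onset at the
largest first-difference modulus and, for transitory signals, the end
where the deviation re-enters a noise band of 3× the MAD of the pre-onset
samples.  Per-ROI SNR estimates divide filtered-signal power by noise
power from the silence intervals of the corrected-but-unfiltered traces.
Calibration maps electroporation fluorescence linearly per ROI,
`V(j,t) = −(EP(j,t)/AP_peak(j))·AP_amp + V_rest` with AP_amp = 120 mV and
V_rest = −80 mV, so zero deflection is rest and a full AP-sized negative
deflection is +40 mV.

## What the tests do and do not show

Every stage is validated on generator loop-backs: the generators emulate
shot noise, bleaching, the spatial potential pattern and per-ROI SNR
structure of real recordings, but not motion, optics (no PSF), camera
EM-gain noise, dye photodamage kinetics, or irregular cell shapes beyond
ellipses.  Passing tests therefore demonstrate the pipeline's signal
processing properties under its stated noise model, not performance on
any particular microscope.  Problem sizes in the routine suite are kept
at desk scale (32 ROIs, 500 frames, tens of replicates), chosen so a full
run completes in minutes; the statistical checks (e.g. SBPC degrading
relative to DBPC, error decreasing with SNR) are asserted on means over
seeded replicate sets.

## Known limitations

* ROIs are static: any motion artifact violates the mixing model.
* The surrogate AP's sharp vertex exaggerates low-pass amplitude loss
  relative to ionic-model waveforms (see above).
* The dmey filter bank is the standard FIR truncation of the Meyer
  wavelet; its ~1 % reconstruction error bounds the fidelity of
  `wPCA`/`wICA` outputs with that wavelet.
* FDPC's step amplitude is statistically collinear with the linear trend
  term over a half-record step; its standard error sets a floor (~10 % at
  −10 dB per-ROI SNR) on stationary-level accuracy that no fitting
  algorithm can beat without more data.
* ImageJ ROI export writes one outer boundary polygon per ROI; ROIs with
  holes round-trip only approximately (a warning is emitted).
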