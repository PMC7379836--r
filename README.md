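# metroidr

Denoising of subcellular fluorescence signals by equal-area ROI
segmentation and blind source separation — an R implementation of the
METROID workflow for voltage-sensitive-dye (VSD) imaging.

## The problem

VSD fluorescence changes by only a few percent per 100 mV, so the mean
trace of a small subcellular region of interest (ROI) is often buried in
photon shot noise (SNR down to −10 dB and below).  Repeating and
averaging trials is impossible for one-shot events such as
electroporation.  `metroidr` is for experimenters who need to recover
membrane-potential waveforms — action potentials (APs) or
electroporation steps — from a *single* fluorescence video.

## The method

1. **MESS** (Morphological Equal-area Standardized Segmentation): the
   cell mask is aligned vertically, split by sequential erosions into an
   inner region holding `n_in/(n_in + n_out)` of the area, and divided
   into `n_out` outer and `n_in` inner quasi-equal-area ROIs that spring
   at standardized places regardless of cell orientation.
2. **Photobleaching correction** per ROI by non-linear least squares on
   one of `A e^{-Bt} + C [− Dt] [− E·u(t − t₀)]`, with input windows
   SBPC (pre-onset), DBPC (all silence intervals) or FDPC (whole record,
   step term absorbing a persistent signal).
3. **Blind source separation**: the n ROI traces are decomposed by PCA
   or FastICA into m ≤ n sources; the source with the highest
   active-interval energy is kept (or chosen manually) and the traces
   are rebuilt through the inverse transformation — optionally after
   hard-thresholding the source's wavelet detail coefficients at
   `K = √(2 ln N)·σ` (wPCA/wICA).
4. **Quantification**: per-ROI SNR estimates, amplitude/correlation
   metrics (`E_r_Amp = (Amp_meas − Amp_true)/Amp_true`, Pearson r,
   RMSE), and calibration to millivolts via
   `V(j,t) = −(EP(j,t)/AP_peak(j))·AP_amp + V_rest`.

Synthetic generators reproduce every ingredient at desk scale — AP and
step sources, zero-mean Poisson(λ = 225) shot noise, random exponential
bleaching, and full artificial videos
`F = BF + g⊙Signal + Bleach(BF,t) + Noise` with per-ROI SNR gains and a
Klee–Plonsey prolate-spheroid electroporation potential field — so the
whole pipeline is verifiable against known ground truth.

## Worked example

Simulate a −10 dB AP video, run the full pipeline, and compare with the
generator's ground truth:

```r
library(metroidr)

spec <- video_sim_spec(kind = "AP", target_db = -10, seed = 1)
sv   <- compose_video(spec)           # video + ROIs + known truth
res  <- metroid(sv$video, sv$mask, run_config(transitory = TRUE, seed = 1))

res$timing
act <- active_frames(sv$timing, spec$fps, 500)
r <- sapply(1:32, function(j)
  cor(res$filtered$traces[j, act], sv$truth$traces[j, act]))
round(c(mean_r = mean(r), mean_snr_db = mean(res$snr_db)), 2)
```

```
#> signal_timing: active [2.51, 2.54] s of 5 s
#>      mean_r mean_snr_db
#>        0.98       -9.39
```

The detected onset (2.51 s) lands one frame after the true 2.5 s onset;
the filtered 32-ROI traces correlate with the noise-free truth at
r ≈ 0.98 even though each raw trace was built at −10 dB, and the per-ROI
SNR estimated from the data reproduces the −10 dB build target (−9.4 dB estimated).

A command-line front end wrapping the same functions lives at
`inst/scripts/metroid.R`
(`Rscript inst/scripts/metroid.R run --video v.tif --fps 100 --transitory`).

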