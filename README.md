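# laminarifc

Cortical-depth resolved analysis of phase-encoded auditory fMRI:
tonotopy and spectral tuning-width mapping from chirp-stimulus BOLD
runs, core/noncore parcellation of the auditory sheet, and
feature-dependent **intrinsic functional connectivity (iFC)** on model
residuals, summarised per depth and region by the decay constant of an
exponential fit.

## Who this is for

Auditory/laminar fMRI researchers who want a tested, self-contained
implementation of the phase-encoded chirp analysis chain — and a
synthetic-data generator with known ground truth, so every stage
(phase maps, tuning widths, parcellation, iFC selectivity) can be
validated by parameter recovery before being pointed at real data.

## The model

**Stimulus.** A 20-s logarithmic chirp (250→4000 Hz, four octaves)
followed by 10 s of silence, repeated 15×/run at TR = 2.5 s; two
rising- and two falling-chirp runs per subject, at five normalized
cortical depths nd ∈ {0.1, 0.3, 0.5, 0.7, 0.9}.

**Phase-encoded mapping.** Per vertex, the Fourier component at the
presentation frequency f_p = 1/30 Hz gives amplitude a and phase φ of a
sinusoidal activation model a·cos(2π f_p t + φ). The model–data
correlation (Fisher-transformed, converted to a standard-normal score
via the exact null of the two-parameter fit) thresholds responsive
vertices at z > 1.65. Rising/falling phases are combined as

    φ_avg = (φ_rc + 2π − φ_fc) / 2

which cancels the hemodynamic delay; φ_avg maps linearly to response
latency and hence to log frequency preference.

**Tuning width.** The run is averaged into one stimulus block, a
Gaussian b + A·exp(−(t−μ)²/2σ²) is fitted, and FWHM = 2√(2 ln 2)·σ is
converted to octaves at the chirp rate (0.2 oct/s).

**Parcellation.** The core is the largest 4-connected patch with mean
tuning width < 1.7 octaves inside the FDR-thresholded (q = 0.01)
functional ROI; the rest of the ROI is noncore.

**iFC selectivity.** After regressing the evoked response out of each
run, within-region pairwise residual correlations are binned by
Δ-frequency (octave edges 0, 0.1875, 0.375, 0.75, 1.5, 3; Fisher-z
averaging) and fitted with y = R₀·e^(−λx). Larger λ = connectivity more
confined to similar-frequency locations. Group inference: Page's trend
test on the binned curves, one-way ANOVA across depths, one-tailed
t-tests with FDR/Bonferroni correction.

## Worked example

```r
library(laminarifc)
cfg <- run_config(n_subjects = 3, depths = c(0.1, 0.9))
out <- run_pipeline(cfg, seed = 5, out_dir = "scratch/run1", verbose = FALSE)
aggregate(lambda ~ region + depth, out$lambda, mean)
#    region depth    lambda
# 1    core   0.1 2.0632224
# 2 noncore   0.1 1.0127821
# 3    core   0.9 1.2336344
# 4 noncore   0.9 0.9814789
out$stats$core_gt_noncore
#   depth            p p_bonferroni
# 1   0.1 0.0008040465  0.001608093
# 2   0.9 0.0035091934  0.007018387
```

The generator planted λ = 2.0 (core) / 1.0 (noncore) at nd = 0.1 and
1.2 / 1.0 at nd = 0.9: the fitted means recover the truth within a few
percent, and the paired one-tailed test detects core > noncore
selectivity at both depths (Bonferroni-corrected over depths). The
parcellation recovered the generative core strip exactly (Jaccard 1.0),
and Page's trend test on the binned Δ-frequency curves rejected the
monotone null at p = 1e-4 (the Monte-Carlo permutation floor).

A command-line front end is in `inst/cli/laminar-ifc`
(`laminar-ifc all --config cfg.json --seed 1 --out results/`).

## Layout

- `R/stimulus.R`, `R/sheet.R` — paradigm, grid geometry, surface smoothing
- `R/synthetic.R` — ground truth + BOLD run generator (known tonotopy,
  tuning widths, exponential residual covariance, delays, confounds)
- `R/phase.R` — Fourier component, activation scoring, delay-cancelling
  phase average, latency debiasing, per-subject feature maps
- `R/tuning.R` — block averaging and Gaussian FWHM tuning widths
- `R/regions.R` — FDR functional ROI, core/noncore parcellation,
  SNR-matched control ROI
- `R/variability.R` — inter-subject and split-half intra-subject SD maps
- `R/ifc.R` — residual iFC, binning, exponential selectivity fit,
  Page's trend test, robustness preprocessing (Butterworth bandpass +
  confound regression)
- `R/group_stats.R` — ANOVA, one-tailed t, FDR/Bonferroni
- `R/pipeline.R` — end-to-end orchestration with config + seeds
- `vignettes/laminar-ifc-methods.Rmd` — the methods vignette
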