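---
title: "Methods: laminar tonotopy and feature-dependent intrinsic connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: laminar tonotopy and feature-dependent intrinsic connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of the science it implements: the
models and their assumptions, the parameters that matter, what the
synthetic generator does and does not emulate, the numerical choices,
and the limitations a user should know about. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## 1. The analysis problem

Auditory cortex is tonotopically organised: preferred sound frequency
varies smoothly along the cortical sheet, with a narrowly tuned,
primary-like *core* surrounded by more broadly tuned *noncore* fields.
With submillimetre fMRI the BOLD signal can be sampled at several
normalized cortical depths (nd = 0.1 ... 0.9 between the white-matter
and pial boundaries), asking whether functional properties — here the
*selectivity* of intrinsic functional connectivity (iFC) with respect
to frequency preference and tuning width — change across depth and
between core and noncore.

The pipeline chains seven stages: (1) phase-encoded mapping of
frequency preference, (2) Gaussian tuning-width estimation, (3)
functional-ROI and core/noncore parcellation, (4) inter-/intra-subject
variability, (5) residual (intrinsic) connectivity against feature
difference, (6) exponential-decay selectivity fitting, and (7) group
statistics. A synthetic generator with known ground truth exercises the
whole chain, so correctness is established by parameter recovery rather
than by eyeballing maps.

## 2. Stimulus model and coordinate system

One block is a 20-s logarithmic chirp from 250 to 4000 Hz followed by
10 s of silence; 15 blocks per run at TR = 2.5 s give 180 volumes and a
presentation frequency f~p~ = 1/30 Hz. Because the sweep is logarithmic
and spans four octaves in 20 s, time within the chirp and octaves are
linearly related at 0.2 oct/s — the single constant used for every
time↔octave conversion (the temporal FWHM of a response bump, the
latency→frequency map).

Latencies in the silent tail (20–30 s) correspond to no stimulus
frequency. They are flagged invalid and the vertex is dropped from
feature maps; no imputation is attempted.

## 3. Phase-encoded mapping and delay cancellation

The Fourier component of a vertex's series at f~p~ defines the
sinusoidal activation model `a·cos(2π f_p t + φ)` (cosine convention,
t = 0 at block onset; the convention is fixed once and shared by the
generator and the estimator). Two conventions deserve explanation:

* **Activation score.** The Pearson correlation between model and data
  is Fisher-transformed (`activation_zscore()`, the atanh of r). For
  *thresholding* we convert the fit to a standard-normal score using
  the exact null distribution of a two-parameter (cosine/sine) fit:
  under the null, R² ~ Beta(1, (n−3)/2), so p = (1−r²)^((n−3)/2) and
  z = Φ⁻¹(1−p). With this calibration, the conventional threshold
  z > 1.65 is one-tailed p < 0.05 *exactly*; on pure-noise synthetic
  subjects the rejection rate is at (or below, after averaging the two
  run directions) the nominal 5%, which the test suite verifies.
  A raw atanh(r) threshold of 1.65 would require r > 0.93 and reject
  essentially every vertex at n = 180.

* **Latency axis of the phase average.** The delay-cancelling average
  φ~avg~ = (φ~rc~ + 2π − φ~fc~)/2 removes any hemodynamic delay that is
  common to both sweep directions — a pure temporal shift adds opposite
  phase lags relative to the frequency axis. Under the cosine
  convention, however, the average maps a response latency L to
  (block + chirp)/2 − L: the falling chirp reverses only the 20-s sweep
  while the 2π term corresponds to the full 30-s block, leaving a
  constant 5-s offset. `phase_to_latency()` is the pure linear
  transform; the constant is removed once inside `map_subject()`.
  The delay-invariance property (recovered latency independent of
  injected delays 0–8 s to well under TR/2) is an acceptance criterion.

### Truncation bias and its correction

The first-harmonic phase of a response bump that is *truncated* — by
the silent tail, or by the edges of the swept frequency range — is
pulled toward the centre of the remaining mass. On the synthetic sheet
this compresses the recovered frequency axis by a measurable factor
(≈0.78 near the sweep ends for typical tuning widths, up to ~0.6
octaves of error at the extremes). The bias is a deterministic function
of true latency and tuning width under the stimulus model, so
`debias_latency()` computes the forward latency→biased-latency mapping
per tuning width and inverts it by interpolation. Raw phase maps remain
the mapping stage's output (they are the field's standard estimator);
the debiased preference is used as the feature axis for connectivity,
where axis compression would otherwise inflate every decay constant by
1/0.78 ≈ 1.28.

## 4. Tuning width

Runs are segmented and averaged into one block per direction; falling
blocks are reoriented onto the rising axis by reversing time about the
chirp window (exact on the sample grid because the 20-s chirp is a
multiple of TR). A four-parameter Gaussian (baseline, amplitude,
centre, σ) is fitted by least squares; FWHM in seconds × 0.2 oct/s is
the tuning width.

Numerical choices:

* **Per-direction fitting.** A hemodynamic delay d shifts the rising
  and reoriented-falling bumps to L+d and L−d; averaging the directions
  before fitting would convolve in the unknown 2d offset and broaden
  every width. Each direction is fitted separately and the widths
  averaged.
* **Response-window restriction.** When the (delay-free) phase latency
  map is available, the subject's delay is estimated as the circular
  mean of (fitted centre − latency) and the Gaussian is refitted using
  only samples inside the delay-shifted 20-s chirp window. Silence
  samples carry no stimulus and would otherwise drag the tails of
  edge-truncated bumps; with the restriction, noiseless recovery is
  exact (to ~1e−6 relative) across the sheet, including half-truncated
  bumps at the sweep edges.
* **Optimisation.** Deterministic initialisation (argmax, σ₀ = 2·TR,
  A₀ = max−min, b₀ = min), L-BFGS-B with box constraints
  (σ ∈ (0, block]), and a Nelder–Mead polish when the line search
  terminates abnormally. Blocks whose peak wraps across the block
  boundary are rotated to centre first.

## 5. Regions

The functional ROI thresholds the across-subject mean z map by
one-tailed Benjamini–Hochberg FDR at q = 0.01, with the anatomical mask
fixing the family size. The core is the largest 4-connected patch of
the group mean tuning-width map (averaged over subjects and depths,
surface-smoothed at 5 mm FWHM) below 1.7 octaves; the remaining ROI is
noncore; the labelling is applied identically at every depth.
4-connectivity is the grid analogue of "spatially continuous" (the
choice is recorded in the labels' provenance). An SNR-matched noncore
control ROI (greedy nearest-SNR selection of exactly |core| vertices,
ties by vertex index) supports the robustness control that core/noncore
differences are not an SNR artefact.

## 6. Residual iFC and the selectivity constant

Per run, the evoked response is regressed out and the residuals of the
four runs are concatenated (per-run regression includes the intercept,
so inter-run offsets cannot inflate correlations). A design decision
that matters:

* **Harmonics.** The printed activation model is the f~p~ sinusoid, but
  the evoked response to a 20-s bump in a 30-s cycle has substantial
  power at 2f~p~, 3f~p~, ... Regressing out only the fundamental leaves
  stimulus-locked residue whose inter-vertex correlation itself decays
  with Δ-frequency; on synthetic data this inflated fitted λ from 2.0
  to ≈3.2. `ifc_analysis()` therefore removes *all* harmonics of f~p~
  up to Nyquist — i.e. the entire block-periodic evoked component — so
  residual correlations measure intrinsic covariance only.
  `regress_out(n_harmonics = 1)` reproduces the literal printed model.

Within each region and depth, all vertex pairs with Δ < 3 octaves enter
the analysis (Δ = |log₂ f₁/f₂| for frequency; |log₂ w₁/w₂| for tuning
width, base 2 chosen for symmetry with the frequency axis). Pairs are
binned at octave edges {0, 0.1875, 0.375, 0.75, 1.5, 3} (half-open
bins), averaged through the Fisher z transform, and fitted with
y = R₀·e^(−λx) by constrained nonlinear least squares (λ ≥ 0; port
algorithm with a log-linear start and an `optim` fallback). Negative
binned correlations are permitted.

* **Bin representative x.** The fit's x for each bin is the *mean Δ of
  the pairs in the bin* rather than the bin midpoint. On a tonotopic
  map that is locally quantized (discrete gradient steps), the
  within-bin Δ mass sits far from the midpoint — e.g. the first bin can
  contain only Δ = 0 pairs — and midpoint-x inflated fitted λ by
  20–30% on ground-truth features, while pair-mean x recovered the
  generative constants to within ~2%. Midpoint remains available as
  `x_mode = "midpoint"`.

Group inference follows the field's conventions: Page's trend test for
the monotone decrease of iFC over Δ bins (within-subject ranks,
L = Σ c_j R_j; normal approximation for N ≥ 12, exact enumeration when
(k!)^N ≤ 2·10⁵, seeded Monte-Carlo permutation otherwise; average ranks
for ties), classical one-way ANOVA across depths (df = (k−1, N−k),
matching how pooled depth profiles are reported; a subject-blocked
repeated-measures form is available), one-tailed t-tests, BH-FDR over
the seven printed depth pairs, and Bonferroni over region-by-depth
comparisons.

### The robustness (preprocessing) control

The control pipeline adds a 6th-order Butterworth 0.01–0.1 Hz bandpass
— implemented in the frequency domain as the squared magnitude response
of the analog prototype, which is exactly the net zero-phase gain of
forward–backward filtering (effective order doubled) — and regression
of six motion plus one white-matter confound series (filtered like the
data). On synthetic subjects with drift and nuisance coupling injected,
the paired fig9-vs-none change in λ is required to lie inside the
Monte-Carlo confidence bound (±1.96·SE of the paired difference across
20 subjects) and within 15% of λ itself. The bound is a CI rather than
1·SE because the change is zero-mean by construction and a 1·SE bound
on a zero-mean estimate fails ~32% of the time regardless of
correctness.

## 7. The synthetic world

`make_ground_truth()` fixes, per configuration: a mirror-symmetric
tonotopy (ln f is a V along the column axis — a low-frequency band
flanked by two high-frequency bands — spanning exactly 250–4000 Hz); a
contiguous narrow core strip (tuning width 1.4 oct inside, 1.9 outside,
straddling the 1.7-oct threshold); per-depth/region decay constants
(default: core 2.0→1.2 from deep to superficial, noncore 1.0 flat — the
qualitative finding the pipeline is designed to detect); per-subject
hemodynamic delays U(3, 7) s (a typical BOLD latency range); evoked
amplitude 1 with residual noise SD 0.1 (the "standard noise" of the
acceptance criteria); baseline residual correlation ρ₀ = 0.6.

`simulate_run()` is the forward model: per vertex, a Gaussian tuning
profile in log₂-frequency (FWHM = the vertex's width) evaluated along
the chirp trajectory, zero in silence, circularly delayed, sampled at
TR; plus residual noise drawn i.i.d. over time from a zero-mean
multivariate normal with Cov(v,w) = σ²ρ₀·exp(−λ·|Δlog₂f|) within a
region, σ² on the diagonal and 0 across regions (Cholesky factor cached
per depth; a 1e−8 diagonal jitter with a warning if the matrix is not
positive definite). Optional components: low-frequency drift
(0.002-Hz cosines with random phase plus a linear term) and scaled
copies of the always-recorded motion/WM nuisance series. The fig9-style
worlds use drift amplitude 0.1 (equal to the noise SD — scanner drift
is typically at least as large as thermal noise at these time scales)
and nuisance gain 0.05; both default to 0.

What the generator does **not** emulate — and hence what a green test
does not establish: folded cortical geometry and geodesic distances,
draining-vein depth biases, Rician or physiological (cardiac/
respiratory) noise, temporal autocorrelation (an AR option was
considered and omitted: the pipeline operates on residual correlations,
which are invariant to common temporal filtering in expectation),
between-subject anatomical variability, and any departure of the true
residual covariance from the exactly exponential family being fitted.
The generative family matching the fitted model is deliberate: it makes
λ recovery a well-posed acceptance test, not evidence that real
auditory cortex decays exponentially.

* **Delay as a pure shift.** No HRF convolution by default: the phase
  average cancels any even-handed delay exactly, and a pure shift
  isolates that property for testing. Shape-level HRF effects
  (undershoot, dispersion) are out of scope.

## 8. Tolerances and degenerate inputs

* Infinite Fisher z capped at atanh(1−1e−12); standard-normal scores at 40.
* Zero-variance series: activation score NA; Gaussian fit invalid;
  paired t on identical samples returns t = 0, p = 0.5 by convention.
* Smoothing is a Sinkhorn-balanced (doubly stochastic) truncated
  Gaussian: constants and the map mean are preserved exactly at the
  sheet boundary; NA vertices are excluded from the kernel support.
* Split-half variability requires ≥ 3/4 of the 2×n_repeats estimates
  valid per vertex; splits are complementary halves over block
  identity, making the measure invariant to block order.
* Monte-Carlo sizes in the test suite follow the stated criteria
  (2000 null tables for Page calibration, 500 replicates for FDR,
  20 subjects for λ recovery); unit tests use smaller worlds sized to
  keep the full suite under ~6 minutes on one CPU.

## 9. Known limitations

The latency debiasing assumes the generator's Gaussian-bump response
family when inverting the truncation bias; on real data with asymmetric
responses the correction would be approximate. The grid sheet is a
stand-in for a reconstructed surface: distances are Euclidean grid
distances and the 4-connectivity parcellation rule is a grid analogue.
Selectivity comparisons across depths inherit whatever depth-dependent
SNR structure the acquisition has; the SNR-matched control ROI
addresses the core/noncore comparison only.
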