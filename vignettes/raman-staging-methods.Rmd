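---
title: "Methods: preprocessing and PCA-LDA staging of single-cell Raman spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: preprocessing and PCA-LDA staging of single-cell Raman spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ramanstage` implements a complete chemometrics workflow for single-cell
Raman spectra of oesophageal cell lines spanning disease progression:
healthy squamous epithelium (HET-1A), Barrett's oesophagus from
non-dysplastic to severely dysplastic (CP-A, CP-B, CP-C, CP-D), and
adenocarcinoma (OE19). This vignette is the package's account of the
science in the code: the models, every tunable that matters, what the
synthetic data do and do not emulate, and the numerical conventions.

## Dataset model

A spectrum is a strictly increasing wavenumber axis (cm⁻¹) with one
intensity per point. Acquisition covers two windows, 300–1800 and
1800–3200 cm⁻¹, generated (and stored) contiguously on one grid with
window membership as metadata; `merge_windows()` joins separately
acquired windows, averaging a duplicated boundary point. Axes are
calibrated against the silicon reference band at 520.5 cm⁻¹ by pure
translation (intensities never change); shifts above 10 cm⁻¹ are applied
but flagged as suspect. Spectra are assembled on a common grid by linear
interpolation — linear rather than spline because it is monotone-safe and
adequate at 1–2 cm⁻¹ spacing — and resampling never extrapolates: a grid
point outside a spectrum's support is an error naming the spectrum,
because silent edge extrapolation would quietly corrupt the EMSC fits
downstream.

## Preprocessing chain

The stage order is frozen:

calibrate → EMSC → baseline → truncate → normalize → smooth → outliers.

Skipping a stage requires an explicit config flag, and every run records
a provenance log with per-stage parameters and per-class counts, so an
omission is always visible.

### EMSC with interferent removal

Each spectrum is decomposed by ordinary least squares as

$$s(\nu) = b\,r(\nu) + \sum_{p=0}^{P} c_p x^p + \sum_k g_k i_k(\nu) + e(\nu)$$

with reference $r$, interferents $i_k$, and $x$ the wavenumber axis
rescaled to $[-1, 1]$ before the polynomial columns are formed (raw
wavenumbers near 10³ raised to powers would make the normal equations
ill-conditioned). The corrected spectrum is
$(s - \sum_p c_p x^p - \sum_k g_k i_k)/b$.

Choices made where the design was open:

* **Reference** — the dataset mean spectrum, computed once *before* any
  correction, and never per class: preprocessing must not see labels, or
  class information leaks into the features before cross-validation.
* **Polynomial order** — default $P = 2$; exposed in the config. Higher
  orders start absorbing broad Raman features.
* **Interferent** — the PDMS (polydimethylsiloxane) chip background,
  supplied as a spectrum on the dataset grid. The package ships a
  *synthetic* PDMS reference (`pdms_reference()`): a deterministic,
  pointwise-defined sum of broad Gaussian bands at the characteristic
  PDMS positions (488, 708, 1262, 1412, 2907 cm⁻¹). It is a stand-in
  constructed for testing, not a measured spectrum, and the same object
  both contaminates generated data and serves as the EMSC interferent
  column.
* **Degeneracy** — a rank-deficient design matrix errors, listing the
  collinear columns; $b \approx 0$ errors; $b \le 0$ is flagged and the
  spectrum passed through uncorrected rather than dropped, so failures
  are auditable.

Because the mean-spectrum reference itself contains the average
interferent contribution, the fitted weight estimates
$g_i - b_i\,\bar g$, not $g_i$; recovery tests account for that shift.

### Morphological baseline correction

Residual fluorescence is estimated by iterated greyscale opening plus
mollifier smoothing. One pass erodes then dilates with a window of
half-width `w` points (default 101), which strips any feature narrower
than the window from the lower envelope, then convolves with a compactly
supported bump kernel $e^{-1/(1-u^2)}$ (width 21 points) to round the
piecewise-flat envelope. Iteration proceeds on `pmin(input, estimate)`
until the estimate changes by less than `tol = 1e-6` (sup norm) or 50
iterations. Numerical conventions:

* Signal ends are padded by linear extrapolation (slope least-squares
  fitted over the outermost points) before both the morphology and the
  convolution, so a sloped fluorescence ramp is not clipped at the
  spectrum edges.
* The final baseline is clipped pointwise to never exceed the input, and
  `corrected + baseline` reconstructs the input to machine precision.
* On noisy spectra the sup-norm criterion at `1e-6` sits below the noise
  floor: after the first few passes the estimate creeps by
  $\sim 10^{-4}$ intensity units per pass (the clipping keeps relaxing
  into noise dips), so the iteration typically stops at the cap and
  returns the final iterate with `converged = FALSE`. That drift is two
  orders of magnitude below the band amplitudes and has no practical
  effect; the flag is information, not an alarm.

### Truncation, normalization, smoothing, outliers

* **Truncation** keeps the closed interval 800–1800 cm⁻¹, the
  fingerprint region dense in diagnostic bands.
* **Normalization** divides by the maximum intensity within ±5 cm⁻¹ of
  the Amide I anchor at 1656 cm⁻¹. The windowed maximum (rather than the
  single grid value) tolerates ±1 cm⁻¹ residual calibration drift. A
  non-positive normalizer is an error: such a spectrum is unusable.
* **Smoothing** is Savitzky–Golay, order 2, window 17 points, delegated
  to `signal::sgolayfilt`; the edge fits handle endpoints, so
  polynomials up to the fitted degree pass through unchanged.
* **Outlier removal** scores each spectrum by squared distance from its
  class mean. Target mode removes the highest scores until `target_n`
  (default 100) remain per class; MAD mode removes scores above
  `median + k·MAD` (default `k = 3`). Ties break by spectrum id, so
  removal is deterministic. The pipeline reports per-class counts both
  before and after removal.

Baseline correction precedes truncation deliberately: the morphological
window then sees the full acquisition range, and edge effects from
truncation cannot bleed into the baseline estimate.

## PCA-LDA classification

PCA is a mean-centred SVD; explained-variance ratios are taken against
the total variance, and each loading's largest-magnitude entry is made
positive so loadings compare deterministically against oracles and
across runs. The default 15 components reflect the spectral setting
where they capture well over 90 % of variance; the CV driver caps the
count at the per-fold maximum and records what it used.

LDA solves $S_b v = \lambda (S_w + \varepsilon I) v$ by symmetric
whitening of the within-class scatter ($\varepsilon = 10^{-6}$ ridge for
numerical stability), keeps up to (classes − 1) axes, and classifies by
nearest class mean in discriminant space, ties broken by class-label
order. Nearest-mean in the whitened discriminant space is equivalent to
the usual linear discriminant rule under equal priors and keeps the
geometry explicit.

Cross-validation is stratified k-fold (default k = 4): within each
class, indices are shuffled under the seed and dealt round-robin, so
per-class fold sizes differ by at most one. **PCA is refitted inside
every training fold** — fitting it once on all data would leak test-set
variance structure into the features; refitting is this package's
convention. Held-out predictions are pooled into one count matrix,
reported row-normalized (rows = true class), so the diagonal is
per-class recall. "Average accuracy" is the *unweighted mean of
per-class recalls*; with near-balanced classes it differs from the
weighted (trace/total) accuracy by well under a point, and both are
reported.

## The synthetic generator

`generate_spectrum()` draws

$$I(\nu) = m \sum_b h_b\,A_b\,\mu_b(\text{stage})\,\phi_b(\nu)
  + \text{baseline}(\nu) + g\,\text{pdms}(\nu) + \epsilon(\nu)$$

* $\phi_b$: pseudo-Voigt line shapes (50/50 Gaussian/Lorentzian), a
  plausible default for condensed-phase Raman bands; configurable.
* Twelve bands at the positions seen in oesophageal single-cell spectra
  (tryptophan 880, phenylalanine/tryptophan 1009, DNA 1089, tyrosine
  1171, Amide III 1250, collagen 1320, CH₂ 1450, cytochrome c 1583,
  tyrosine/tryptophan 1610, Amide I 1656, CH₃ 2881 and 2980 cm⁻¹).
* Stage multipliers $\mu_b$ follow progression scores (HET-1A 0, CP-A
  0.30, CP-B 0.38, CP-C 0.46, CP-D 0.55, OE19 1.00) times a signed
  per-band trend: DNA, tryptophan and CH₃/lipid bands rise monotonically
  toward cancer, cytochrome c falls. The *directions* encode the
  qualitative biology; the magnitudes are package conventions — no
  quantitative fold change between these cell lines is on record, so no
  default here claims fidelity to the real lines. The scores place
  adjacent dysplastic grades close together and the carcinoma line far
  from all of them, so healthy-vs-cancer separation is large while
  adjacent-grade separation is small — the difficulty structure the
  classifier analyses are designed around. The per-band heterogeneity
  default (below) was calibrated to preserve exactly that structure:
  at sdlog 0.2 the Amide-I heterogeneity, turned into global scale
  jitter by the Amide I normalization, aligned with the progression
  direction and blurred the dysplasia/cancer boundary, so the default
  is 0.1.
* Noise model defaults: multiplicative scatter $m$ lognormal (sdlog
  0.1); per-cell per-band heterogeneity $h_b$ lognormal (sdlog 0.1);
  fluorescence baseline a random cubic with coefficients uniform on
  `0.2 × [0, 1]` — smooth enough to exercise, not dictate, the
  morphological corrector; PDMS weight $g$ uniform on [0.1, 0.5];
  additive noise sd 0.01 (about 1 % of the Amide I amplitude).
* Randomness: one root seed; each spectrum's substream seed derives
  deterministically from (stage index, replicate index), so a fixed
  seed gives bit-identical datasets and any subset is independently
  reproducible. Ground truth ($m$, $g$, baseline coefficients, seeds)
  is returned alongside for recovery tests.

What the generator does **not** emulate: cosmic-ray spikes, detector
response and optics (defocus, spot size), cell-cycle or
microenvironmental covariance between bands, wavenumber jitter, and any
real inter-line biochemical magnitude. Passing tests therefore
demonstrate that the *pipeline machinery* is correct and that the
*qualitative* difficulty structure is recovered — not that real cell
lines would classify at these rates.

## Verification design and problem sizes

The test suite checks every operation against an independent oracle
where one exists: EMSC against a direct normal-equation solve on
noise-free constructions; PCA against a covariance eigendecomposition;
LDA against a brute-force generalized eigensolver and against
`MASS::lda` projections; the baseline corrector against analytic
peak-plus-polynomial constructions. Property tests cover round-trip
I/O, fold-partition invariants, determinism under fixed seeds, and
leakage-freedom of the CV (corrupting a spectrum cannot change its
fold-mates' predictions).

Two calibrated end-to-end checks close the loop, at sizes chosen to
keep the statistics sharp:

* **Bayes recovery** — two classes differing only by a fixed band-sum
  offset under isotropic Gaussian noise have analytic Bayes accuracy
  $\Phi(\lVert\delta\rVert/2\sigma)$. With a fingerprint-only grid at
  20 cm⁻¹ spacing (51 points) and 300 spectra per class, the
  cross-validated PCA-LDA accuracy over 10 seeds is required to lie
  within 3 percentage points of the 0.85 Bayes rate. The low dimension
  and large n are deliberate: finite-sample PCA/LDA loss grows with
  p/n, and at 51/600 the classifier sits close enough to the Bayes
  bound for the comparison to be meaningful.
* **Qualitative structure** — a default six-line dataset (50 cells per
  line, 2 cm⁻¹ grid) run through the full chain must show no
  healthy or dysplastic class misassigned to OE19 at more than 10 %,
  and higher pairwise CV accuracy for HET-1A vs OE19 than for CP-A vs
  CP-D.

## Known limitations

* The EMSC interferent weight is identified only relative to the mean
  reference's interferent content (see above); absolute weights need an
  interferent-free reference.
* The morphological baseline assumes bands are narrow relative to the
  structuring window; bands broader than ~2·`w` grid points would be
  partially absorbed into the baseline.
* Nearest-mean LDA assumes shared within-class covariance; strongly
  class-dependent covariance (plausible for a heterogeneous carcinoma
  line) would favour quadratic rules the package deliberately omits.
* File input supports plain two-column text/CSV only; vendor binary
  formats are out of scope.
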