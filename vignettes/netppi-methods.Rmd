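---
title: "Modelling modulatory network coupling with netppi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling modulatory network coupling with netppi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Resting-state fMRI decomposes the brain into large-scale networks — the
anterior and posterior default mode networks (aDMN, pDMN), the salience
(SAL), dorsal attention (DAN) and left/right executive (LECN, RECN)
networks — whose pairwise correlations are informative but static. A
*physiophysiological interaction* (PPI) model asks a different question:
is the coupling between two networks *modulated* by a third? For a target
signal $y$ and two network time courses $x_{N1}, x_{N2}$, the model is

$$ y = \beta_0 + \beta_{N1} x_{N1} + \beta_{N2} x_{N2} +
      \beta_{PPI}\, x_{N1} x_{N2} + \varepsilon . $$

$\beta_{PPI} > 0$ means the connectivity between $y$ and one network grows
with the activity of the other. This is not a partial correlation: the
main-effect terms already control the linear relationships, and only a
genuinely multiplicative dependence loads on $\beta_{PPI}$ (the suite
verifies that purely additive dependence leaves $\beta_{PPI}$ at its null
distribution).

`netppi` implements the full pipeline — cleaning, neural-level interaction
construction, network-wise and voxel-wise GLMs, and group inference — plus
a synthetic cohort generator with known ground truth, which is the
package's acceptance surface.

## The interaction must be built at the neural level

BOLD is a convolution of neural activity with a hemodynamic response
function (HRF), and convolution does not commute with multiplication:
$ (h * n_1)(h * n_2) \neq h * (n_1 n_2) $. The interaction regressor is
therefore built by the deconvolve–detrend–multiply–reconvolve recipe
(`build_ppi_regressor()`): both cleaned BOLD series are deconvolved to the
neural level, linearly detrended, multiplied pointwise, and the product is
convolved back with the HRF.

### The HRF

`canonical_hrf()` uses the standard double-gamma form: a gamma density
with delay 6 s minus one with delay 16 s scaled by 1/6, unit dispersions,
32 s support, peak-normalized. Delay $d$ and dispersion $s$ map to shape
$d/s$ and scale $s$, so the kernel vanishes at lag 0 and peaks at
$\approx 5$ s. These values are the de-facto convention of the major fMRI
packages; the source analysis names no parameters, so the canonical set is
declared here and recorded in the kernel object.

### Deconvolution

Deconvolution is ill-posed. The neural signal is expanded in an
orthonormal DCT-II basis up to Nyquist and its coefficients estimated by
penalized least squares against the causal convolution operator — a ridge
prior on the coefficients, in the spirit of the empirical-Bayes shrinkage
schemes used for this purpose. Two numerical choices matter:

* **Frequency-weighted penalty.** Basis column $j$ (frequency $f_j$)
  carries weight $1 + (f_j/f_0)^4$, $f_0 = 0.05$ Hz. A flat ridge lets
  high-frequency components fit the final ~kernel-length samples, which
  causal truncation leaves weakly determined; the curvature-type weight
  extrapolates the tail smoothly instead. With it the noiseless
  round trip `deconvolve(convolve(x))` achieves $r > 0.99$ for
  band-limited signals at 228 samples, TR 2 s (the acceptance bound);
  interior samples round-trip at $r \approx 1$.
* **GCV-selected strength.** The overall penalty $\lambda$ is chosen by
  generalized cross-validation on a log grid ($10^{-8}$–$10^6$), since the
  original procedure's hyperparameters are unspecified. A fixed `reg` can
  be passed; `reg = 0` gives the truncated-SVD pseudoinverse.

Deconvolution runs at the series' own TR (no microtime upsampling) —
adequate at TR = 2 s and a simpler, testable contract. The operator's SVD
depends only on (kernel, length) and is cached, which is what makes the
1000-replicate calibration runs cheap.

## Cleaning

`clean_network_series()` enforces the fixed order: (1) OLS residualization
against six rigid-body motion parameters, the WM first principal
component, the CSF first principal component, and an always-included
constant (residualizing without an intercept would bias the mean);
(2) DCT high-pass at 0.01 Hz (100 s period). Both steps are idempotent.
Compartment masks are built from tissue-probability maps with a *strict*
threshold (`> 0.99`), so partial-volume gray matter is excluded and voxel
counts are reproducible. Rotations are assumed to be radians (the
realignment-output convention), with a degrees flag.

Network series are scaled to unit variance before PPI construction
(switchable), making $\beta_{PPI}$ comparable across pairs; the
reconvolved PPI regressor and all non-constant columns are mean-centered
before entering the GLM.

## The two analyses

**Network-wise** (`run_networkwise_all()`): for each of the
$\binom{6}{2} = 15$ pairs, each of the 4 non-member networks serves as
target — 60 effect rows per subject, with target identity kept (so "aDMN
vs SAL×RECN" and "RECN vs aDMN×SAL" are distinct, reciprocity being a
finding of interest). Group inference is a cross-subject one-sample t on
the per-subject $\beta_{PPI}$, Bonferroni-controlled at
$0.05/60 = 8.33\times10^{-4}$ with a strict inequality. The network-wise
design carries no nuisance columns — nuisance was removed beforehand.

**Voxel-wise** (`voxelwise_ppi()`): per-voxel OLS with eleven columns —
constant, two main effects, the PPI regressor, WM, CSF, six motion
parameters — with an implicit 1/100 Hz high-pass applied by residualizing
*both* data and design against the same DCT set (one shared cutoff
constant serves the 0.01 Hz and 1/100 Hz statements, which are the same
number). Group maps are one-sample t fields per ±1 contrast.

**Cluster inference** (`cluster_inference()`): height threshold at
$p < 0.001$ (one-sided per contrast), 18-connectivity components (the
convention of the relevant software family; 6/26 available), cluster
extent p from the Gaussian-RFT approximation
$P(\text{extent} \ge k) = \exp(-\beta k^{2/3})$ with $\beta$ set by the
expected cluster size implied by the resel count (mask volume over the
product of per-axis FWHMs), then Benjamini–Hochberg across the clusters of
one map at $q = 0.0033$ (per-map, not pooled across the 15 analyses — the
source is ambiguous; per-map is the default here). The t field enters the
Gaussian formulas through the height quantile; exactness is not claimed at
low df or near-voxel smoothness — instead the null simulation bounds the
false-positive behaviour (≤ 2/20 null scenes with any surviving cluster,
observed 0–1 in development runs). Smoothness comes from the classical
standardized-residual derivative estimator (`estimate_smoothness()`),
which recovers an applied 8 mm FWHM within ±20% and reports ≈ 1.2 voxels
on unsmoothed noise.

`fisher_z()` / `correlation_table()` reproduce the simple-correlation
companion analysis: per-subject Pearson r per pair, Fisher z, group
one-sample t, Bonferroni over 15.

## The synthetic world

`synthetic_config()` states the emulated world once: 64 subjects, 228
volumes at TR 2 s (230 acquired minus 2 discarded), six networks. Source
networks are unit-variance Gaussian processes with squared-exponential
autocovariance, length scale 4 s — slow, resting-state-like dynamics; the
real data offer no generative model, so this is declared, not inferred.
A coupling target is
$\sum b\,x_{src} + \sum c\,x_{a} x_{b} + \sigma\,\eta$ with white Gaussian
innovation $\eta$ ($\sigma =$ `noise_sd`, default 1 — unit innovation
against unit-variance sources, fixed a priori). Targets may not feed other
couplings (no cycles). BOLD adds: HRF convolution; cosine drift at periods
≥ 128 s (below the 0.01 Hz cutoff); measurement noise partially aligned
with the subject's random-walk motion trace; WM/CSF compartment leakage.
Everything is deterministic from `(seed, subject_index)`.

The generator's forward model is exactly the model class the estimator
assumes — that is the point: estimator bias on matched data vanishes as
noise does, so parameter recovery is a meaningful acceptance surface. A
green suite therefore establishes internal consistency and calibration,
*not* robustness to the things real data add: spatially structured
physiological noise, HRF variability across subjects and regions,
head-motion artefacts beyond a linear trace, or ICA estimation error in
the network time series themselves.

`simulate_volume_scene()` plants the voxel-wise ground truth on a
40×40×24 grid of 3 mm voxels (small but RFT-viable): six non-overlapping
network blobs, a disjoint interaction region carrying
$c \cdot (h * n_1 n_2)$, WM/CSF compartments, white voxel noise.

## Inference-level calibration

Per-subject OLS t-statistics on HRF-autocorrelated series are
anti-conservative (no prewhitening — matching the original analysis).
The pipeline's actual inference is the cross-subject one-sample t on
per-subject betas, which is exactly calibrated under the null regardless
of within-subject autocorrelation (betas are mean-zero Gaussian across
independent subjects). The acceptance suite measures this directly: 1000
replicate null cohorts give a rejection rate at raw $\alpha = 0.05$ inside
the exact binomial 99% interval. Eight subjects per replicate are used —
the group t is df-exact at any cohort size, and this keeps 1000 full
pipeline replicates near a minute. Subject-level calibration is also
verified in the regime where it does hold (white-noise target).

## Degenerate inputs and tie-breaks

Zero-variance series are errors wherever a correlation or scaling is
implied (PCA extraction, correlation table, one-sample t with zero sd).
Rank-deficient designs name the offending columns. The PCA sign is fixed
by the largest-magnitude loading. Cluster peaks report 0-based voxel
indices (plus mm via the affine in file outputs). An empty
supra-threshold set yields an empty cluster table, not an error.
`build_compartment_mask` uses strict `>`.

## Known limitations

* The deconvolution prior is a stand-in for the unspecified original
  empirical-Bayes schedule; results should be compared across `reg`
  settings for sensitivity.
* Gaussian-RFT cluster p-values are approximations; at the smoothness of
  unsmoothed synthetic scenes they are conservative, which the null
  criterion tolerates but which costs power for small clusters.
* No prewhitening at the subject level; single-subject p-values from
  `networkwise_ppi` should not be interpreted in isolation.
* NIfTI support covers uncompressed NIfTI-1 with the common datatypes
  only (validated against nibabel); no .nii.gz, no NIfTI-2.
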