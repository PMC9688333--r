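---
title: "Methods: preprocessing, PLS-DA and validation for SERS biofluid classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: preprocessing, PLS-DA and validation for SERS biofluid classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serschemo)
```

## The problem

Label-free SERS of pleural fluid yields, per patient, hundreds of mapping
spectra (700–1800 cm⁻¹ Raman shift) in which disease-associated changes in
protein, lipid and nucleic-acid bands are superimposed on a large, smooth
autofluorescence background, detector noise, occasional cosmic-ray spikes,
and a patient- and substrate-dependent overall enhancement gain. The
analysis task is binary diagnosis (cancer vs control) from these spectra,
with honest per-patient error estimates and an interpretable account of
*which* wavenumber bands carry the discrimination.

`serschemo` implements that analysis as composable stages:
`preprocess_pipeline()` → `cross_validate()` / `fit_plsda()` →
`vip_scores()`, orchestrated end-to-end by `run_case_study()` on synthetic
data from `generate_dataset()`.

## Preprocessing model and parameters

Per spectrum, in order:

1. **Despiking** (`despike()`). Cosmic rays hit single detector bins, so
   they produce extreme second differences. Bins whose modified z-score
   (median/MAD) of the second difference exceeds 8 are replaced by linear
   interpolation of clean neighbours. The threshold is deliberately far
   above noise (a Gaussian bin reaches 8 with probability ~1e-15) so smooth
   spectra pass through bit-identically. If more than 5% of bins flag, the
   input is not a spiked spectrum but something pathological, and the stage
   errors instead of rewriting it. Despiking runs *before* the baseline fit
   so a spike cannot drag the baseline upward.

2. **AsLS baseline removal** (`asls_baseline()`). The background is modelled
   as the minimizer of a weighted least-squares term plus a second-difference
   roughness penalty, with asymmetric weights (`p` for points above the
   current fit, `1 - p` below) iterated to a fixed point. Small `p` makes
   the fit hug the lower envelope, i.e. pass under the Raman bands while
   tracking the broad fluorescence. Defaults `lambda = 1e5`, `p = 0.01`,
   at most 15 reweighting iterations with a relative weight-change tolerance
   of 1e-6 — standard operating points for Raman fingerprint baselines at
   ~1 cm⁻¹ spacing; `lambda` trades stiffness against bleed into broad
   features (the package asserts baseline roughness is non-increasing in
   `lambda`).

3. **Savitzky–Golay smoothing** (`savgol_smooth()`, window 11, order 3).
   Local least-squares polynomial smoothing: preserves band shape up to
   cubic structure within an 11 cm⁻¹ window while averaging down noise.
   Edges are handled by evaluating the terminal-window polynomial, so
   polynomials up to the filter order are reproduced exactly everywhere.

4. **Fingerprint crop** (`crop()`, closed interval 735–1700 cm⁻¹) — the
   region used for chemometrics; edge regions outside it carry filter
   transients and little biochemical signal.

5. **Mean normalization** (`normalize_mean()`). "Mean-normalized" is read
   here as division of each spectrum by its own mean intensity over the
   cropped range, removing per-acquisition scale (laser power, focus,
   hot-spot strength). A vector-norm alternative would differ only by a
   per-spectrum constant; the mean convention keeps intensities on an
   interpretable "fraction of mean signal" scale. Normalization runs
   *after* baseline removal: dividing before stripping the baseline would
   let the (biochemically meaningless) fluorescence amplitude set the
   scale. `preprocess_config(normalize = "none")` switches it off.

Column **mean-centering** is deliberately *not* part of the pipeline: it is
a model-fitting step, computed on training folds only and applied with the
training means to held-out spectra (`mean_center()` returns the vector for
exactly this purpose). Centering on the pooled data would leak test-set
information into training.

## PLS-DA

`fit_plsda()` is PLS1 NIPALS against a single 0/1 response column — the
natural coding for a binary problem (a two-column dummy response adds
nothing for two classes). Each latent variable maximizes covariance between
the centered spectra and the centered class coding; X and y are deflated
between components. Prediction adds the training response mean back and
thresholds the continuous score at 0.5, the midpoint of the coding.

The number of latent variables is not fixed a priori: `cross_validate()`
selects it per outer fold by inner 5-fold subject-stratified
cross-validation over 1..10 components, maximizing spectrum-level accuracy
with ties broken toward the smaller model (a deliberately conservative
one-standard-error-style tie-break without the variance estimate). A fixed
`ncomp` can be supplied instead, which is what the fast tests do.

**VIP** (`vip_scores()`) uses Wold's sum-of-squares-weighted formula; the
algebraic identity mean(VIP²) = 1 makes "VIP > 1" a scale-free selection
rule, and `extract_vip_bands()` reports maximal contiguous runs above the
threshold as closed intervals at grid resolution (1 cm⁻¹ here; no sub-bin
interpolation, because band edges sharper than the grid are not
identifiable from gridded data). `pca_lda_classify()` provides the
classical PCA + Fisher-discriminant comparator.

## Validation design

Splitting is at **subject** level: all mapping spectra of a patient travel
together between training and test, because spectra of one patient are far
more alike than spectra of two patients and spectrum-level splitting would
largely measure patient re-identification. A per-run assertion enforces
that no subject sits on both sides of any fold. Spectrum-level evaluation
remains available (`level = "spectrum"`) for comparison.

A held-out subject's prediction is the **mean of its spectra's continuous
scores** rather than a majority vote: the mean is smoother at small spectrum
counts and remains a continuous quantity that the ROC threshold sweep can
use. Sensitivity is defined with the cancer group positive. Fold ROCs are
averaged **vertically** (TPR interpolated on a fixed FPR grid, 0 to 1 in
steps of 0.01) and the summary AUC is the arithmetic mean of fold AUCs —
so the reported mean AUC is exactly the average of per-fold areas, not the
area of the averaged curve (the two agree closely for smooth curves).

## The synthetic study generator

`generate_dataset()` emulates the structure the analysis assumes:
≥ 500 mapping spectra per subject over 3 substrate locations (scaled down
in tests), Lorentzian bands — the natural Raman line shape — at the
fingerprint positions assigned to phenylalanine, lipid, nucleic-acid,
CH₂/CH₃ and amide modes, with multiplicative class effects of 1.3–1.6 on
the bands reported as discriminative for pleural-fluid lung-cancer
diagnosis; a broad autofluorescence background (three Gaussians of FWHM
≥ 300 cm⁻¹, subject-jittered) overlapping the bands; iid Gaussian detector
noise; Poisson single-bin positive spikes of 10–50 × noise SD; and a
log-normal per-subject gain, because SERS enhancement varies
multiplicatively with spot and substrate rather than additively.

Unreported quantities were fixed once at values a Raman practitioner would
call realistic and are stated in `sim_config()` defaults: band FWHM
12 cm⁻¹, peak amplitudes 300–600 counts, baseline amplitude 2000 counts
(background dominating the bands, as fluorescence does), noise SD 20
counts, spike rate 0.05 per spectrum, subject gain SD 0.15 (log scale).
The generator records where class effects were injected
(`ground_truth_bands()`), which is what recovery tests score against.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: correlated (pink/fixed-pattern) noise, peak
position and width shifts between patients, chemical matrix effects that
couple band intensities, substrate batch effects, and any physically
calibrated enhancement model. Perfect synthetic separability at large
effect sizes says the machinery is correct, not that real pleural fluid
separates this cleanly.

## Numerical choices

- The AsLS inner system is pentadiagonal and solved exactly per iteration
  by a banded LDLᵀ factorization (compiled), cross-checked in tests against
  a dense direct solve. Because the system's conditioning grows like
  `lambda / p` (~1e7 at defaults), two steps of iterative refinement with an
  extended-precision residual are applied, and the input is detrended
  (affine fit removed, rescaled) before fitting — the objective is exactly
  affine-equivariant, so this changes nothing mathematically while removing
  the large-magnitude component that roundoff scales with. A by-product is
  that constant and ramp inputs reproduce exactly.
- Savitzky–Golay is delegated to `signal::sgolayfilt`, verified in tests
  against brute-force per-window polynomial fits, edges included.
- ROC thresholds sweep every distinct score; ties step the curve
  diagonally, which makes the trapezoid AUC equal the tie-corrected
  Mann–Whitney statistic (asserted to 1e-10 in tests).
- Degenerate inputs fail loudly rather than silently: single-class
  responses, uncentered descriptor matrices, requests past the achievable
  rank (the error names the rank), non-positive row means before
  normalization, fold plans that orphan a class, and spectra that do not
  cover the resampling grid.
- Round-robin dealing within class after a seeded shuffle guarantees
  per-fold class counts within one subject of proportionality.

## Problem sizes

Tests run the full chain at reduced scale — typically 10 subjects per class
with 10–50 spectra each (the null-calibration check uses 20 replicates of
10×10), against the generator's scientific default of ≥ 500 spectra per
subject — chosen so the whole suite exercises every stage end-to-end in
well under a minute per property while leaving the scientific structure
(subject nesting, class balance, band positions) intact. The acceptance
script uses 10 subjects per class × 50 spectra (1000 spectra × 966
wavenumbers).

## Known limitations

- PLS-DA here is strictly binary (PLS1); multiclass discrimination and
  sparse/orthogonal PLS variants are out of scope.
- Band intervals are reported at grid resolution; adjacent true bands
  closer than the grid spacing merge.
- Subject-level ROC curves in 10-fold CV rest on very few units per fold
  (1–3 subjects per class); the vertical average is correspondingly step-like
  at small cohort sizes.
- The despiker assumes spikes are single-bin; multi-bin detector artefacts
  survive it (the Savitzky–Golay stage attenuates but does not remove
  them).
- Mean normalization couples band intensities: an intensity change at one
  strong band shifts every normalized intensity slightly, so VIP can flag a
  band whose raw intensity is class-independent. This is a property of the
  normalization convention, not a bug; difference spectra
  (`group_mean_difference()`) should be read alongside VIP.
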