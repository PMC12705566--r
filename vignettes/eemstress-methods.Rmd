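---
title: "Methods: EEM fluorescence analysis for pollutant-stress classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEM fluorescence analysis for pollutant-stress classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Plants under pollutant stress change the composition of the organic
compounds their roots release. The fluorescent fraction of these root
exudates — humic-like, fulvic-like and protein-like (tyrosine/tryptophan)
material — can be profiled non-destructively with excitation–emission
matrix (EEM) fluorescence: a 2-D landscape of intensity over every
excitation/emission wavelength pair. `eemstress` implements a complete
analysis chain for such data: scatter removal, two feature-extraction
routes (classic peak picking and PARAFAC), classification of stress level
from spectra or features, and Shapley-value attribution of the trained
models. Because no public spectra accompany the design this package
targets, a synthetic generator with full ground truth is a first-class
component: every stage of the pipeline is validated against data whose
composition is known exactly.

The reference design has seven treatment groups — an unstressed control
plus three polymer types (PET, PS, PVC) at two doses (10 and 100 mg/L) —
with 48 spectra per group (336 total), recorded on a grid of excitation
220–550 nm in 5 nm steps by emission 240–750 nm in 1 nm steps
(67 × 511 = 34,237 cells per spectrum).

## Scatter removal

Raw EEMs are dominated by three chemically uninformative ridges:
first-order Rayleigh scatter along em = ex, second-order Rayleigh along
em = 2·ex, and the water Raman line displaced from the excitation line by
a fixed wavenumber shift. With the default shift of 3400 cm⁻¹ (the water
O–H stretch), the Raman line of a 350 nm excitation falls at

$$\lambda_{Raman} = \frac{1}{1/\lambda_{ex} - \tilde\nu \cdot 10^{-7}} \approx 397\,\mathrm{nm}.$$

Preprocessing is a fixed four-stage composition:

1. **mask** all cells within a half-width of any ridge (defaults 15 nm
   for both Rayleigh orders, 10 nm for Raman);
2. **interpolate** masked runs linearly along each emission row, extending
   the nearest value at row edges (interpolation runs along emission only —
   the same treatment a 1-D emission spectrum receives);
3. **smooth** each emission row with a centred moving average
   (11 points by default), with symmetric shrinking windows at the edges;
4. **zero** the non-physical triangle em < ex (Stokes' rule: emitted
   photons cannot carry more energy than the exciting photon), last, so
   interpolation cannot leak intensity into it. Any negatives left by
   smoothing are clipped to zero.

No instrument-specific band widths are prescribed by the measurement
itself, so the defaults above are explicit, conventional choices exposed
in `scatter_config()`; reproducibility requires printed numbers rather
than "suitable" ones. Inner-filter correction, Raman-unit normalisation
and blank subtraction are out of scope.

On generated data the pipeline's output can be compared with the
scatter-free ground truth: outside a 5 nm guard band around the ridges
the RMS reconstruction error stays below 1.5× the additive noise standard
deviation (in practice well below — smoothing removes more noise than the
interpolation bias adds back).

## Peak features

The seven classic peak windows (A, M, C, D, B, T, N — UV/marine/visible
humic acid, fulvic acid, tyrosine-, tryptophan- and phytoplankton-like
material) are quantified as the **mean** intensity over all grid cells in
the window, the statistic that is robust to single-pixel noise; the
window maximum is available as an alternative. Point-valued positions
(e.g. peak A's excitation at 260 nm) become degenerate windows snapped to
the nearest grid line. Peak extraction is linear in intensity and local
to its window, and both properties are asserted as tests.

## PARAFAC

The dataset is stacked into a sample × excitation × emission tensor and
decomposed trilinearly,

$$x_{ijk} \approx \sum_{f=1}^{F} a_{if}\, b_{jf}\, c_{kf},$$

with non-negativity on all three modes, since scores and spectra of
fluorophores are physically non-negative. The solver uses HALS
(hierarchical alternating least squares) column updates, which are
monotone in the residual sum of squares; the fit trace is recorded and
monotonicity is asserted in tests. Scale indeterminacy is resolved by
unit-norm excitation/emission loading columns with magnitudes absorbed
into the sample scores, so an ideal model's Tucker core is the
superdiagonal identity. Defaults: 10 random restarts for a final fit,
tolerance 10⁻⁸ on the relative change in residual fraction, at most 500
sweeps. The emission axis may be decimated (default 4× in the pipeline)
before fitting; Gaussian emission profiles are much wider than 4 nm, so
decimation shrinks the computation without moving any component.

Rank selection uses two diagnostics:

* **Core consistency (CORCONDIA)** — the least-squares Tucker core for
  the fixed loadings compared against the superdiagonal identity,
  `100·(1 − ‖G − T‖²/‖T‖²)`; near 100 at an appropriate rank,
  collapsing (possibly far below 0) when over-factored. A rank-deficient
  factor matrix makes the diagnostic meaningless, so that case returns a
  degeneracy flag rather than a number. For F = 1 the converged ALS
  solution makes the single-element core exactly 1, hence the diagnostic
  exactly 100.
* **Split-half similarity** — samples are randomly halved, both halves
  fitted, components greedily matched by Tucker congruence on the
  concatenated excitation+emission loadings, and the split scored as
  100 × mean matched congruence. The reported value is the **worst** of 3
  random splits: a stable chemistry must survive every split. No
  structured split scheme is imposed; random halves with congruence
  matching is the neutral default.

The selected rank is the largest candidate with split-half similarity
≥ 95% and core consistency ≥ 60. The 95% bar is the conventional
published threshold for split-half agreement; 60 is a deliberately
permissive core-consistency floor whose job is only to reject clear
over-factoring. On the default 5-component synthetic dataset the
procedure selects 5 from candidates 3–6.

Held-out samples are featurised without refitting by non-negative least
squares of the unfolded EEM onto the Khatri-Rao structure of the fixed
loadings (`project_scores()`).

## The attention classifier

The classifier is a small transformer encoder operating on token
sequences built from the input view:

* **2-D EEM**: zero-pad to multiples of the patch size (default 8 × 32
  cells), cut non-overlapping patches, flatten — the default grid gives
  9 × 16 = 144 patches;
* **1-D emission spectrum**: non-overlapping 16-point windows
  (511 points → 32 tokens);
* **feature vector** (7 peaks or F PARAFAC scores): a single token, so
  the same architecture serves all three representations.

Patches are linearly embedded to d = 64, a fixed sinusoidal positional
encoding is added and a learned classification token is prepended. Each
encoder block is pre-norm: layer normalisation → multi-head scaled
dot-product attention (4 heads, head dimension d/h) → residual; layer
normalisation → two-layer ReLU MLP → residual. Layer normalisation is
used instead of batch normalisation so per-token statistics do not depend
on batch composition — spectra have widely varying intensity ranges. The
classification head is a linear–ReLU–dropout–linear map from the class
token; dropout (default 0.1) acts only during training.

Inputs are scaled before patching, with the scaling fitted on the
training set and stored in the model: feature vectors are z-scored per
column, spectra and EEMs are divided by their global standard deviation
(division only, so zero-padded cells stay zero). Raw fluorescence
intensities span hundreds of arbitrary units, and gradient steps sized
for unit-scale inputs stall without this.

Training minimises softmax cross-entropy with Adam. Backpropagation is
implemented in the package itself (hand-derived gradients for layer norm,
attention and the MLPs) and verified against central finite differences.
All randomness — initialisation, shuffling, dropout — derives from the
configured seed, so training is exactly reproducible, and inference is
deterministic (dropout off).

Model sizes are intentionally small (defaults d = 64, depth 2, MLP width
128; the small-scale pipeline preset halves these): a dataset of a few
hundred spectra cannot support more capacity, and training must run on a
single CPU. Baselines — k-nearest-neighbour (vote fractions over the k
nearest by Euclidean distance) and random forest — expose the identical
probability-vector prediction contract.

Class labels are the three concentration levels within one polymer
(control / 10 / 100 mg/L), matching the per-polymer three-class design;
polymer identification is not the task.

## Evaluation

Splits are stratified by class: 2/3 calibration, 1/3 validation, with
5-fold stratified cross-validation folds assigned inside the calibration
set (the source design states no ratios; these conventional defaults are
recorded in the configuration). From a confusion matrix with rows = true
class, one-vs-rest metrics are

* sensitivity(c) = 100·TP(c) / row-total(c),
* specificity(c) = 100·TN(c) / (TN(c) + FP(c)) with FP counted
  **column-wise** (off-row predictions into column c),
* accuracy = 100·trace / total.

The column-wise false-positive convention is the only definition
consistent with all printed cells of the worked three-class tables the
tests reproduce (e.g. specificity 87.5 = 42/48 for the 100 mg/L class
when six foreign samples land in that column). Accuracy equals the
prior-weighted mean of sensitivities; that identity is asserted on random
matrices.

`excitation_sweep()` trains the 1-D classifier per excitation wavelength
and records validation accuracy, locating the wavelengths that carry
class information; on synthetic data whose discriminative component sits
at a known excitation, the accuracy curve peaks there.

## Shapley attribution

Feature attributions use the SHAP masking convention: the value of a
coalition S is the model output with features outside S replaced by their
calibration-set means (a single fixed background, for determinism). The
explained output is the predicted probability of the instance's true
class — probabilities are interpretable on [0, 1], unlike logits. With
p ≤ 15 features the attribution is exact coalition enumeration
(`2^p` model calls, batched), which satisfies efficiency, dummy and
symmetry by construction and is tested against brute-force enumeration
over all p! orderings for small p. For per-wavelength attribution
(p in the hundreds) a permutation-sampling estimator with per-feature
Monte-Carlo standard errors is provided; each sampled permutation
telescopes, so efficiency survives sampling. Summaries report mean |φ|
per feature, overall and per true class, with ties broken by catalog
order.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes:

* five Gaussian-profile fluorophores at conventional positions
  (305/425, 285/355, 375/475, 360/430 nm, plus one broad long-wavelength
  composite component), widths 15–30 nm so the peak windows read distinct
  components. Gaussian (not log-normal) profiles are chosen deliberately:
  separable profiles make the noise-free tensor *exactly* trilinear, the
  property PARAFAC recovery tests need;
* multiplicative treatment effects per (component, polymer, dose):
  controls fixed at 1, low dose in 0.6–0.9 (suppressed exudation), high
  dose in 1.2–1.8 (enhanced), with strength ordered PS > PVC > PET at
  high dose — polymer identity is encoded purely through effect-size
  patterns;
* per-sample, per-component lognormal score scatter (σ = 0.08) for
  between-sample biological variation, first- and second-order Rayleigh
  and Raman ridges, and additive Gaussian measurement noise (σ = 10
  intensity units against component amplitudes of 400–1000, i.e. a
  signal-to-noise ratio well above 20), clipped at zero.

These defaults *are* the study conditions of every stochastic test and of
the acceptance computation; they were fixed once, from what a
fluorescence practitioner would call realistic and clearly separated
treatment effects, and are not tuned per test. What the generator does
not emulate — inner-filter effects, pH and quenching chemistry,
instrument drift, non-Gaussian band shapes, dose-reversal exceptions for
individual components — bounds what passing tests show: they validate the
algorithms against their own assumptions, not the field performance of
the method on real exudates. Dose-reversal patterns can be configured via
the effect table, but the default implements the dominant pattern only.

## Problem sizes and numerical choices

The test-suite and the end-to-end reproduction run at reduced scale,
chosen as the smallest sizes at which every qualitative property is still
expressed: 8 samples per group (56 spectra) for dataset-level tests,
emission decimation 8× for rank-selection tests, encoder width 16–32 for
classifier tests. The acceptance computation runs the full 336-sample
design with 4× emission decimation. Miniature tensors
(20 × 10 × 15-scale) carry the oracle-equivalence and recovery tests.

Degenerate inputs are handled explicitly: fully masked emission rows are
an error naming the excitation wavelength; zero tensors are rejected by
the PARAFAC fitter; an all-background coalition returns the base value;
empty datasets yield empty tables. HALS columns that collapse to zero are
re-seeded with a tiny positive value to keep factors well-defined.

## Known limitations

* The attention model is CPU-bound pure R; it is sized for hundreds of
  spectra, not tens of thousands.
* Exact Shapley is limited to 15 features; beyond that only the sampling
  estimator applies.
* PARAFAC assumes complete (preprocessed) tensors; missing-data ALS,
  Tucker3 and PARAFAC2 variants are out of scope.
* The split-half scheme uses random halves; structured schemes (e.g.
  contrasting experimental blocks) may be stricter for real campaigns.
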