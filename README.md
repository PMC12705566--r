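# eemstress

Analysis of excitation–emission matrix (EEM) fluorescence spectra of plant
root exudates for non-destructive classification of pollutant stress.

## The problem

Plants under abiotic stress — here, microplastics (PET, PS, PVC) in the
root environment — change the composition of the organic material their
roots release. The fluorescent fraction of these root exudates
(humic-like, fulvic-like, tyrosine- and tryptophan-like compounds) can be
profiled without touching the plant: an EEM records fluorescence
intensity over every pair of excitation (220–550 nm, 5 nm steps) and
emission (240–750 nm, 1 nm steps) wavelengths, a 67 × 511 landscape per
sample. `eemstress` turns a collection of such spectra, labelled by
polymer type and dose (0 / 10 / 100 mg/L), into a stress-level
classifier with attributable decisions.

The pipeline:

1. **Scatter removal** — first/second-order Rayleigh (em = ex, em = 2ex)
   and water Raman ridges (wavenumber shift 3400 cm⁻¹, so excitation at
   350 nm scatters near 397 nm) are masked, filled by linear
   interpolation along emission rows, smoothed by moving average, and the
   non-physical em < ex triangle is zeroed.
2. **Feature extraction** — two routes:
   classic *peak picking* (mean intensity over the seven conventional
   windows A, M, C, D, B, T, N), and *PARAFAC*, the trilinear tensor
   decomposition
   `x_ijk ≈ Σ_f a_if b_jf c_kf`
   with non-negativity on all modes, validated by core consistency
   (CORCONDIA) and split-half Tucker-congruence analysis.
3. **Classification** — a compact patch-attention (transformer-encoder)
   model `softmax(QKᵀ/√d_k)V` over tokens cut from full EEMs, 1-D
   emission slices, or feature vectors; KNN and random-forest baselines
   share the same probability contract. Metrics are one-vs-rest
   sensitivity/specificity and accuracy on stratified
   calibration/validation splits.
4. **Attribution** — exact (coalition-enumeration) Shapley values for
   feature models, permutation-sampled values for per-wavelength
   attribution, summarised as mean |φ| rankings overall and per class.

Because no public spectra accompany this design, a synthetic EEM
generator with full ground truth (separable Gaussian fluorophores,
dose-dependent loadings, scatter ridges, measurement noise) is part of
the package; every stage is tested against what was actually put in.

## Worked example

```r
library(eemstress)

# simulate a labelled study: 7 groups x 8 samples, then remove scatter
sim <- generate_eem_dataset(n_per_group = 8, seed = 1)
ds  <- preprocess_dataset(sim$dataset)

# peak-method features
peaks <- build_peak_table(ds)
head(peaks[, c("sample_id", "A", "M", "C", "T", "polymer", "concentration")], 4)
#>          sample_id     A     M     C     T polymer concentration
#> 1 CONTROL_000_s001 66.76 600.8 569.8 559.9 CONTROL             0
#> 2 CONTROL_000_s002 59.66 549.1 541.4 569.0 CONTROL             0
#> 3 CONTROL_000_s003 71.61 624.8 565.7 534.1 CONTROL             0
#> 4 CONTROL_000_s004 65.87 585.9 591.2 489.5 CONTROL             0

# PARAFAC on the sample x excitation x emission tensor
X   <- dataset_tensor(ds, decimate_em = 8)
fit <- fit_parafac(X, F = 5, n_restarts = 3, seed = 1, max_iter = 300)
fit
#> <parafac_model> F = 5, fit_error = 0.00376, 300 iterations
core_consistency(fit, X)      # 78.0
split_half(X, 5, n_splits = 3, seed = 1, n_restarts = 2, max_iter = 200)
#> 97.4   (worst-split similarity, percent)

# three-class stress-level model for the PET arm, from peak features
pet    <- peaks[peaks$polymer %in% c("CONTROL", "PET"), ]
splitv <- split_dataset(pet$concentration, seed = 1, k_folds = 4)
res <- evaluate_classifier(
  feature_matrix(pet), pet$concentration, splitv,
  function(x, y) train_attention_classifier(
    x, y, attention_config(embed_dim = 32, depth = 1, mlp_hidden = 64,
                           epochs = 80, learning_rate = 5e-3, seed = 1),
    type = "features"))
res$confusion
#>      predicted
#> true  0 10 100
#>   0   2  0   1
#>   10  0  3   0
#>   100 0  0   3
res$metrics
#> accuracy: 88.89%
#>   class 0: sensitivity 66.67%, specificity 100.00%
#>   class 10: sensitivity 100.00%, specificity 100.00%
#>   class 100: sensitivity 100.00%, specificity 83.33%
```

Reading the output: the five-component PARAFAC model explains all but
0.4% of the tensor's sum of squares; a split-half similarity of 97.4%
(above the conventional 95% bar) says the same five spectral shapes are
recovered from independent halves of the samples. In the small PET
validation set one control sample was predicted as 100 mg/L, which costs
the 0 mg/L class sensitivity (2/3 = 66.67%) and the 100 mg/L class
specificity (5/6 = 83.33%), while overall accuracy is 8/9 = 88.89%. At
the full design size (48 samples per group) the feature models reach
100% validation accuracy on well-separated synthetic data — see
`pipeline_reproduce()`, which chains
simulate → preprocess → features → PARAFAC → train/evaluate → explain
and writes every artifact (CSV/JSON) plus a metrics report to a
directory.

A thin command-line wrapper over the same functions ships in
`inst/exec/eemstress` (subcommands `simulate`, `preprocess`, `peaks`,
`parafac`, `train`, `evaluate`, `sweep`, `explain`, `reproduce`).

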