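# emdeeg

Classification of pre-seizure vs. seizure EEG segments with empirical
mode decomposition (EMD), ensemble EMD (EEMD), and a hybrid
intrinsic-mode-function (IMF) selection procedure.

## What it does

Scalp EEG during an epileptic seizure carries high-amplitude rhythmic
3–5 Hz activity that the pre-seizure background lacks. `emdeeg` turns
that difference into a classification pipeline for one-minute, 100 Hz,
single-channel EEG segments:

1. **Decompose** each segment into IMFs by cubic-spline sifting
   (`emd()`), optionally with noise-ensemble averaging to reduce mode
   mixing (`eemd()`), or into db4 wavelet subbands as a baseline
   (`dwt_subbands()`).
2. **Select** the IMFs that best represent the signal. Four metrics
   score every IMF — energy
   `E_i = Σ |IMF_i[n]|²` (high is better), Pearson correlation with
   the source signal (high is better), a Kullback–Leibler-style
   power-spectral distance `Σ_k log(S_x(ω_k)/S_IMF(ω_k))` (low is
   better), and the one-sample t-test p-value of zero mean (high is
   better). The four order vectors per segment are stacked into a
   ranking matrix (1280 × 16 on the default 16-subject study) and the
   histogram of first-priority indices picks the top `k = 3` IMFs
   (`build_ranking_matrix()`, `consensus_select()`).
3. **Featurize** the selected components: time-domain (energy, mean,
   skewness, kurtosis), spectral (total power, spectral moments
   `M_j = Σ ω_k^j S(ω_k)`, spectral entropy) and nonlinear
   (rescaled-range Hurst exponent, Higuchi fractal dimension with
   `k_max = 30`) banks (`build_feature_table()`).
4. **Classify** with stratified 5-fold cross-validation over SVM,
   k-nearest neighbours (k = 5, Euclidean), Gaussian naive Bayes and
   logistic regression, reporting ACC/SEN/SPE/PRE/F-score per fold and
   as means (`cross_validate()`), plus a left/right hemisphere
   accuracy summary (`hemisphere_summary()`).

A seeded synthetic generator (`generate_dataset()`) emulates the
clinical study layout — 16 subjects × 10 bipolar channels × 2 one-minute
epochs = 320 labeled segments — so the entire pipeline runs with no
external data. `generate_fgn()` produces exact fractional Gaussian
noise for validating the Hurst estimator. Segments can also be read
from delimited text with a JSON manifest or from EDF files
(`read_segments()`).

## Worked example

```r
library(emdeeg)
cfg <- pipeline_config(decomposer = "emd",
                       generator = generator_config(n_subjects = 4, seed = 1),
                       classifiers = c("knn", "naive_bayes"), seed = 1)
rep <- run_pipeline(cfg)
print(rep$ranking_matrix)
print(rep$selection)
print(rep$feature_tables$combined)
for (cl in names(rep$cv_results$combined)) print(rep$cv_results$combined[[cl]])
```

prints

```
<ranking_matrix> 320 rows x 16 columns (4 metric rows per segment)
<selection_result> selected IMFs (priority order): IMF1, IMF3, IMF2
<feature_table> 80 segments x 33 features (0 dropped)
<cv_result> knn, 5-fold CV: ACC 100.00%, F 100.00%
<cv_result> naive_bayes, 5-fold CV: ACC 100.00%, F 100.00%
```

Four subjects give 4 × 10 × 2 = 80 single-channel segments and hence
320 ranking rows (4 metric rankings each). The consensus selects IMF1,
IMF3 and IMF2 — the first IMFs carry the discriminative high-frequency
and seizure-band oscillations. On the combined 33-column feature table
(3 IMFs × 11 features) both classifiers separate the synthetic classes
perfectly at the default effect size; lowering
`generator_config(effect_size = ...)` toward 0 drives accuracy to
chance. `pipeline_config(output_dir = ...)` additionally writes the
ranking matrix, selection histogram, feature tables, per-fold CV
results and a run log to disk. A command-line front end with
`simulate`, `decompose` and `run-all` subcommands is installed at
`inst/cli/emdeeg`.

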