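---
title: "Simulating and decoding block-design fMRI with surfdecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and decoding block-design fMRI with surfdecode}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

surfdecode is a self-contained laboratory for block-design multivoxel
pattern analysis (MVPA). It simulates BOLD time series for a four-condition
surface-property experiment (glossy `G`, glossy-control `GC`, rough `R`,
rough-control `RC`), runs the full decoding pipeline — quality control, GLM
voxel selection, pattern extraction, linear-SVM leave-one-run-out
cross-validation — and computes empirical permutation-null significance
baselines plus the accompanying group statistics. This vignette documents
the model and the methodological choices; see the README for a quick tour.

```{r setup, message = FALSE}
library(surfdecode)
```

## The experimental design

A main-experiment run lasts 368 s at a repetition time (TR) of 2 s: after
4 discarded dummy volumes, 23 blocks of 16 s each (184 retained volumes).
Seven blocks are fixation and sixteen are experimental — each of the four
conditions appears four times, in a randomised order subject to the
constraint that fixation follows experimental blocks 3, 5, 8, 11 and 13.

```{r design}
sched <- build_design(design_spec(), run_id = 1, seed = 1)
head(sched, 5)
table(sched$label)
```

The default study has 9 runs per participant (the control design uses
`design_spec(n_runs = 10)` with 6 participants). A somatosensory localiser
(`build_localiser_design()`) alternates 20 air-on/air-off blocks.

## The signal model

For voxel $v$ of a run,

$$y_v(t) = \beta_0\,\bigl(1 + r_c(t)\,\tfrac{a + A\,P_{vc}}{100}\bigr)
          + d(t) + \varepsilon_v(t),$$

where $r_c(t)$ is the condition-$c$ block boxcar convolved with a unit-peak
double-gamma haemodynamic response, $a$ is a shared percent-signal task
response, $A P_{vc}$ is a fixed voxel-by-condition pattern (the decodable
signal), $d(t)$ is a slow sinusoidal drift, and $\varepsilon$ is AR(1)
noise. With `pattern_amplitude = 0` the conditions are statistically
exchangeable, which is what null-boundary simulations use.

One parameter deserves a note. The HRF kernel has unit peak *per impulse*,
so convolving it over a 16-s block overshoots the nominal amplitude by a
factor of about 2.5. The default `shared_amplitude = 0.2` (percent signal)
was chosen so that a default run's global-signal variance lands around
0.09–0.13 %² — comfortably below the 0.23 %² run-exclusion threshold while
still producing a visible task-locked global response. At
`shared_amplitude = 0.5` every run would fail QC.

## Pipeline conventions

* **Quality control.** `exclude_runs()` drops runs whose *global signal
  variance* — the variance over time of the mean-across-voxels
  percent-signal-change series — exceeds 0.23 %².
* **Population moments.** Variances and SDs throughout the package
  (z-scoring, QC, image statistics) divide by $n$, not $n-1$, so that
  small hand-computed oracles are exact. At 184 volumes the distinction is
  negligible.
* **Voxel selection.** A task-versus-baseline OLS contrast t-map selects
  the top `n_voxels` positive-t voxels (`mode = "top_positive"`), or all
  voxels significant at `alpha` for the localiser (`mode =
  "significant"`).
* **Patterns.** Each kept run is z-scored per voxel over time; block
  patterns average 8 consecutive volumes starting 4 s (2 TR) after block
  onset, compensating haemodynamic delay; the mean pattern of each run is
  then subtracted (per-run centering).
* **Decoding.** A linear C-SVC with $C = 1$ in leave-one-run-out
  cross-validation. When a contrast pools conditions (Matte = GC ∪ RC),
  training classes are balanced by subsampling the majority class — *within
  each training run* — to the run's minority count. Run stratification
  matters: an unstratified draw leaves the subsampled class with uneven run
  representation and measurably biases the classifier against predicting
  it (null accuracy drifts ≈ 0.3 points above chance). Test folds are
  never subsampled.

## The permutation null

Printed significance baselines are empirical: condition labels are
shuffled within runs and the whole decoding repeated, 1000 times, and the
baseline is the nearest-rank upper 95th percentile of the distribution of
group-mean accuracies.

The labels are shuffled **independently for each test fold** ("per test"),
not once per permutation. The distinction is not cosmetic. With a single
shuffle reused across folds, a labelling that happens to admit a good
global separator beats chance in *every* fold, so fold outcomes acquire
positive covariance through their shared training runs and the null is
over-dispersed (per-participant SD ≈ 0.075 instead of the binomial 0.059
for 72 tests). Per-fold shuffling makes fold outcomes independent and the
group-mean null attains the width implied by the total test count, which
is what the printed boundaries reflect. `shuffle_labels()` is still
exported for users who want a dataset-level shuffle explicitly.

```{r null, eval = FALSE}
study <- simulate_study(design_spec(),
                        effect_spec(n_voxels = 100, pattern_amplitude = 0),
                        n_participants = 16, seed = 1, localiser = FALSE)
prep <- prepare_study(study, selection = "task", n_voxels = 100)
nul  <- study_permutation_null(prep, "G_vs_R", n_perm = 1000, seed = 2)
nul            # boundary ~ 52.3 %
autoplot(nul)
```

Expected boundaries (16 participants × 9 runs, 1000 permutations): about
52.3 % for the balanced contrasts (`G_vs_R`, `GC_vs_RC`) and about 51.9 %
for `G_vs_M` (12 tests per fold). The 6-participant × 10-run control
design gives about 53.8 % and 53.1 % respectively — fewer participants
widen the null faster than the extra run narrows it.

## The SVM solver

The C-SVC is a small Rcpp implementation of SMO (sequential minimal
optimisation) with second-order working-set selection, operating on a
precomputed Gram matrix. A 1000-permutation group null needs on the order
of $10^6$ SVM fits (1000 permutations × 16 participants × 9 folds), and
reusing one Gram matrix per participant across all folds and permutations
makes that minutes of CPU instead of hours. Equally important, the
balancing subsamples and per-fold shuffles draw from R's RNG stream, so an
entire study-level analysis is reproducible from a single `seed`. The test
suite cross-checks the solver against `e1071::svm` on random problems via
the primal objective; at our tolerance of 1e-8 the optima agree to about
four significant figures (ours marginally lower, since libsvm's default
tolerance is 1e-3).

## Group statistics and image statistics

`one_sample_t_one_tailed()` (with Bonferroni correction),
`rm_anova_two_way()` (repeated-measures ANOVA via `aov()` with an
`Error(subject/(A*B))` stratum) with `tukey_hsd()` post-hocs,
`wilcoxon_signed_rank()` (exact for ≤ 12 tie-free pairs) and `dprime()`
(log-linear-corrected) cover the group-level analyses. `image_stats()`,
`radial_log_spectrum()` and `spectrum_difference()` compute the
stimulus-image statistics (mean luminance, RMS contrast, skewness, and
RMS differences of radially averaged log-amplitude spectra);
`generate_stimulus_image()` renders simple shaded-sphere stimuli for the
four surface classes.

## Limitations

The simulator is a statistical, not physiological, model: one "ROI" of
independent voxels, no spatial autocorrelation, no motion artefacts, and a
shared HRF across voxels. Decoding accuracies from simulated signal
therefore say nothing about real cortex; what *is* faithful to the
experimental design — because it is data-independent — is the permutation
machinery: fold structure, test counts, and the resulting null widths and
significance boundaries.
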