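---
title: "Transductive stress regression from wearable BVP and GSR: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transductive stress regression from wearable BVP and GSR: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsvr)
```

# The problem

Wrist-worn sensors deliver two peripheral channels that track sympathetic
arousal: blood volume pulse (BVP, photoplethysmography, 128 Hz) and
galvanic skin response (GSR, skin conductance, 4 Hz). Under mental stress
the inter-beat interval and the BVP amplitude fall, while skin conductance
rises and discrete skin conductance responses (SCRs) become more frequent
and larger. The task is a *regression*: estimate a continuous stress level
in [0, 1] once per second from the last 3 seconds of signal.

Two properties of multi-subject physiological data defeat the obvious
approach of pooling everyone's windows into one regression model:

* **Between-subject dispersion.** Baseline conductance, pulse amplitude,
  and the direction and magnitude of each feature's response to stress
  differ strongly across people, so subjects form well-separated, sometimes
  overlapping clusters in feature space, and one feature vector can mean
  different stress levels for different people.
* **Label outliers.** Continuous affect labels are noisy; a few mislabeled
  examples near the test point can dominate a support-vector fit, which is
  built on structural risk minimization and is therefore sensitive to
  exactly those examples.

# The model

## Instance-weighted ε-SVR

The core object is the ε-insensitive support vector regression with a
per-example penalty. For training examples $(x_i, y_i)$, $i = 1,\dots,L$,
and weights $\Omega_i \in \{0, 1\}$,

$$\min_{\omega, b, \xi} \tfrac12\|\omega\|^2
 + C\sum_{i=1}^{L}\Omega_i(\xi_i + \xi_i^*)$$

subject to the usual ε-tube constraints. Its dual is the standard SVR dual
with the box constraints rescaled per example:
$\alpha_i, \alpha_i^* \in [0,\, C\,\Omega_i]$. Consequently an example with
$\Omega_i = 0$ has $\beta_i = \alpha_i - \alpha_i^* = 0$ *exactly*, and the
fit coincides with a plain ε-SVR on the $\Omega_i = 1$ subset. This
reduction is not an implementation shortcut but a theorem about the dual,
and the test suite verifies it coefficient-wise (within $10^{-6}$) and
prediction-wise (within $10^{-8}$) on random instances.

The dual is solved by sequential minimal optimization in C++: maximal
violation picks the first index, a second-order (largest analytic decrease)
rule picks the second, and iteration stops when the KKT gap falls below
`tol` ($10^{-8}$ by default; every fitted model in the test suite has gap
$< 10^{-6}$). The bias is the midpoint of the optimality interval, which
equals the free-support-vector value whenever free support vectors exist.
An independent dense interior-point solution (kernlab's `ipop`) of the same
QP is used in the tests as an oracle, never as the implementation.

## Neighborhood selection in kernel space

For a test instance $z$, squared distances in the implicit feature space
are computable from kernel values alone:
$\kappa_i = K_{ii} - 2K(x_i, z) + K(z, z)$. The neighborhood
$\sigma$ of size $N$ minimizes

$$\sum_{i\in\sigma} \kappa_i \;+\;
  \rho \sum_{i\in\sigma} \frac{|y_i - \operatorname{median}(y)|}
  {\operatorname{mad}(y)},$$

cluster cohesion in feature space plus a robust outlyingness score in label
space (raw, unscaled MAD). The weight vector is then
$\Omega_i = \mathbf 1[i \in \sigma]$ and the local model is fitted and
evaluated at $z$. Each test instance gets its own $\sigma$ and its own
regressor (batch size 1); predicting $m$ instances costs $m$ small QPs of
$2N$ variables each, which is why the solver's small-problem path matters
more than its asymptotics.

**How the minimum is computed.** If median and MAD were recomputed for
every candidate subset the problem would be combinatorial. The package
fixes the statistic on a local candidate pool: stage 1 takes the
`pool_multiplier * N` (default $4N$) κ-nearest training examples; stage 2
computes median/MAD of the *pool's* labels, scores each candidate
$\kappa_i + \rho\,d_i$, and takes the $N$ smallest (ties to the lower
index). Given pool-level statistics the objective is separable, so stage 2
is exactly optimal for that statistic — the tests confirm equality with
exhaustive search over all $\binom{L}{N}$ subsets on small instances. Where
the governing statistic should live (full training set, pool, or subset) is
genuinely open; the pool convention keeps the estimator local (a global
median would be meaningless under strong between-subject dispersion) while
remaining tractable and testable.

**Degenerate cases.** When all pool labels agree, MAD is 0 and every
dispersion score is defined as 0 — identical labels present no outliers to
penalize. Ties in κ or in the combined score resolve to the lower training
index, making selection fully deterministic.

## Training modes

* **ST-SVR** (subject-dependent): k-fold cross-validation inside one
  subject; each test window is predicted transductively from the subject's
  remaining folds.
* **T-SVR** (subject-independent): the pool is every other subject's
  examples plus the test subject's non-test folds.
* **Baselines:** a global inductive ε-SVR (the weighted solver with all
  weights 1) and ordinary least squares, trained on the same pool, under
  the same folds.

`compare_models()` runs all four under one shared fold assignment and pools
absolute errors over subjects before reporting MAE and the population SD of
absolute errors. The baselines default to pooled training (the same data
the T-SVR sees) so that the transductive/inductive contrast is a model
contrast, not a data contrast; `baseline_scope = "per_subject"` restricts
them to within-subject data instead.

# Features

Each 3 s window yields 21 features (`feature_names()`):

| group | band | features |
|---|---|---|
| BVP beats | low | IBI mean, IBI population SD (s) |
| BVP spectral | low | zero-lag third-order cumulant c₃ |
| BVP moments | low | mean, population SD |
| GSR peaks | high & low | SCR count, mean amplitude above window minimum |
| GSR spectral | high & low | c₃ |
| GSR derivatives | high & low | d¹ mean/SD, d² mean/SD, negative-slope proportion |

**Band split.** A periodized orthogonal wavelet packet transform (analysis
operators are double shifts of the db4 scaling/QMF pair; synthesis is the
transpose, so reconstruction is exact for even lengths) returns the
lowest-frequency packet node reconstruction as `low` and the sum of all
remaining nodes as `high`; by linearity the two add back to the input
exactly. Level 5 at 128 Hz puts the BVP low band at roughly 0–2 Hz —
keeping the pulse fundamental (0.9–1.7 Hz) and discarding the dicrotic
notch; level 2 at 4 Hz puts the GSR low band at roughly 0–0.5 Hz, the
tonic component, leaving fast phasic structure in the complement. Inputs
whose length is not a multiple of $2^{\text{level}}$ are symmetrically
extended and truncated after reconstruction.

**Diastolic detection.** Naive minimum search on raw BVP is confounded by
the dicrotic notch; even on the low band, the 8-tap db4 filter's wide
transition band leaves shallow residual dips. `ibi_features()` therefore
anchors on the unambiguous structure: systolic peaks (prominent maxima
above the band midrange, at least `min_separation` = 0.3 s apart, a 200 bpm
ceiling), with the diastolic point as the minimum between consecutive
peaks. IBI statistics use the population SD, as do all window statistics,
for determinism across window lengths.

**Third-order cumulant.** $\hat c_3(\tau_1,\tau_2) = \frac1L \sum_n
\tilde x(n)\tilde x(n+\tau_1)\tilde x(n+\tau_2)$ on the demeaned band; the
exported feature is the zero-lag value (the third central moment), which
captures the non-Gaussian asymmetry of pulse and SCR waveforms that
amplitude spectra discard. The full lag lattice (`cumulant_lattice()`) is
available for inspection; its 2-D DFT is the bispectrum, provided for
visualization, not as a feature.

**Normalization.** Min–max per feature column, fitted on training data,
clipped to [0, 1] at application time; constant columns map to 0. Raw
interactive-protocol labels 1–8 (congruent segments 1–4, incongruent 5–8 by
difficulty) map to [0, 1] by $(y-1)/7$, which is what makes the 0.5
dichotomization cut-off and the LS/MS/HS thirds well defined. Min–max
scaling also bounds the influence of slow GSR baseline drift on the
low-frequency cumulant, the one feature sensitive to it.

**Open readings.** Two entries of the feature table are ambiguous in the
field's usual shorthand. "Negative slope" is exported as the *proportion*
of negative first differences (a drift-insensitive shape feature); the
mean/SD of negative-slope segment durations is a defensible alternative.
BVP statistical moments are computed on the low band, consistent with the
band annotation of the neighboring features.

# Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| window / hop | 3 / 1 | s | operational real-time setting; per-channel overrides possible |
| wavelet, levels | db4; BVP 5, GSR 2 | — | band targets above |
| `min_separation` | 0.3 | s | 200 bpm physiological ceiling |
| `prominence_fraction` | 0.05 | fraction of window range | SCR peaks must rise above band ripple |
| `N` | 5 | examples | cross-validated operating value; smaller overfits, larger underfits |
| `rho` | 1.0 | — | balances the two objective terms; 0 disables outlier rejection |
| `pool_multiplier` | 4 | — | pool of 4N candidates: local enough for a meaningful median, large enough to leave N inliers |
| `C`, `epsilon` | 1, 0.1 | — | LIBSVM-convention defaults |
| kernel | RBF, γ = 1/d | — | LIBSVM convention; linear and polynomial available |
| folds | 5 | — | evaluation harness default |

The canonical hyperparameter search grid is $2^{-8}, 2^{-7.5}, \dots, 2^8$
(33 values per parameter), exhaustively crossed in `grid_search_cv()` with
ties resolved toward the smallest values.

# The synthetic-data module

The generators exist so that every claim above is testable without any
recordings; they emulate the *statistical structure* the method assumes,
not calibrated physiology.

* `gen_bvp_signal()`: a phase-locked cardiac cycle (systolic Gaussian plus
  a smaller dicrotic wave, diastolic trough at the cycle boundary), IBI
  $0.9 - 0.25\,\text{stress}$ s with per-beat jitter, amplitude falling
  linearly in stress, additive noise. Beat times are returned as ground
  truth; over 100 windows with IBI in [0.6, 1.1] s the recovered mean IBI
  errs by about 1.4 sample periods on average.
* `gen_gsr_signal()`: a smooth tonic baseline (random walk low-passed over
  4 s) rising with stress, plus Poisson SCRs (rate 0.05–0.3 /s, amplitude
  0.2–0.8 µS, both increasing in stress) with fast rise (0.75 s) and slow
  decay (2.5 s). Event times are ground truth; well-separated injected
  events are recovered from the low band within ±1 count.
* `gen_multisubject_features()`: labels drawn from the normalized 1–8 set
  (optionally thinned geometrically at the high end by `imbalance`, the
  skew real affect datasets show); features are a shared linear+quadratic
  response to the label plus subject-specific offsets (sd 1.0 per unit
  heterogeneity), response deviations (slopes sd 0.6, curvatures sd 0.8 per
  unit), and observation noise (sd 0.1). `heterogeneity = 0` is the
  homogeneous limit in which pooled and within-subject training coincide.
* `gen_outlier_scenario()`: a label-coherent cluster plus feature-adjacent
  examples carrying labels near the top of the scale, with ground-truth
  flags.

**What the defaults encode.** At `heterogeneity = 2` the subject offsets
dominate the within-subject response after normalization, and the response
maps conflict across subjects. In that regime a pooled inductive fit is
*biased* — no single function is compatible with all subjects — while the
local models are merely noisy, which is the phenomenon the transductive
design targets. The design was chosen to make that mechanism present, not
cosmetic: with mild heterogeneity or near-noiseless features a pooled RBF
machine simply memorizes each cluster and inductive fitting wins, and the
package reproduces that too (the homogeneous-limit tests).

**What passing tests do not show.** The generators have no motion
artifacts, no sensor dropout, no respiration coupling, no non-stationary
label noise, and their stress→physiology couplings are linear by
construction. Benchmark MAEs on synthetic data say nothing about absolute
accuracy on real recordings; only the *relative* behavior (locality,
outlier rejection, pooled-fit degradation under heterogeneity) transfers as
a claim.

**A caveat on ST vs T.** Under the default strong-separation conditions
the pooled (T) neighborhoods are nearly always drawn from the test
subject's own examples, so ST-SVR and T-SVR frequently tie to the fourth
decimal, and either may edge out the other on a given seed; across seeds
the ordering ST ≤ T < pooled ε-SVR ≤ LR holds in the large majority but
not universally (the 20-seed benchmark reports the observed fraction).

# Numerical choices

* Dual solver tolerance $10^{-8}$ (KKT gap), iteration cap $10^6$;
  non-convergence is an error, not a warning.
* Weights outside [0, 1] are rejected; zero-weight examples are removed
  before the QP so their $\beta_i = 0$ holds exactly, not to rounding.
* κ values are clamped at 0 from below (they are squared norms; kernel
  round-off can produce $-10^{-16}$).
* Half-open window intervals $[t_0, t_0 + w)$ on each channel's own sample
  grid prevent off-by-one drift between 128 Hz and 4 Hz channels; the
  window label is the label-track value at the window *end* (the window
  summarizes the signal leading up to its end; event boundaries inside a
  window are resolved in favor of the state being entered).
* LS/MS/HS boundaries are $[0, \frac13)$, $[\frac13, \frac23)$,
  $[\frac23, 1]$; values outside [0, 1] clip with a warning.
* The high/low count ratio is rounded to two decimals; an empty low class
  reports `Inf`.
* Fold assignment is the only randomness in evaluation and is seeded;
  selection and fitting are deterministic.

# Problem sizes

The verification battery runs at desk scale: solver-oracle agreement on
instances of up to 30 examples, exhaustive selection on pools of up to 12,
signal round trips on 100 four-second windows, and the model-comparison
benchmark on 20 datasets of 5 subjects × 60 windows. These sizes make the
full suite and the acceptance script run in minutes on one core while
keeping every oracle exact.

# Known limitations

* The per-instance QP makes prediction latency linear in the number of
  test instances; there is no batch transduction (a shared σ for several
  test points) and no incremental update when training data grows.
* The pool-level median/MAD convention is one of several defensible
  readings of the selection objective; subset-level statistics would
  require combinatorial search.
* Scaling features on the full dataset before cross-validated comparison
  (as `normalize_dataset()` conveniences do) leaks the feature ranges
  across folds; fit the scaler on training folds via
  `fit_scaler()`/`apply_scaler()` when that matters.
* No artifact rejection or EDA tonic/phasic deconvolution; heavily
  contaminated wearable data needs preprocessing upstream of
  `extract_features()`.
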