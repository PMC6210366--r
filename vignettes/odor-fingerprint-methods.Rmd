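---
title: "Odor-fingerprint feature mining: models, parameters and design choices"
author: "odorprint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Odor-fingerprint feature mining: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odorprint)
```

## The problem

A metal-oxide (MOS) e-nose records, for each odor sample, the voltage
response of 16 partially selective gas sensors over several minutes of
headspace exposure. Each sensor responds to many volatiles and each volatile
excites many sensors, so classification rests on the joint response pattern —
the *odor fingerprint* — rather than on any single channel. Two practical
obstacles shape the pipeline: sensor drift (the zero level and gain of a MOS
sensor wander over days to months) and feature redundancy (a fused
time/frequency feature set carries strongly correlated columns that slow and
sometimes hurt the classifier).

`odorprint` implements the full chain: drift-suppressing preprocessing,
fused AV/MV features, VIP- and PCA-based selection, Kennard–Stone
partitioning and RF/PNN classification, plus a synthetic recording generator
that stands in for instrument data.

## Sensor readout model

Each sensor of resistance $R_p$ is read through a series load $R_l$:
$V_o = V_{ref} R_l / (R_p + R_l)$ (`divider_output()`). The sensitivity
$|dV_o/dR_p| = V_{ref} R_l / (R_p + R_l)^2$ (`divider_sensitivity()`) is
maximal at $R_l = R_p$ — the theoretical optimum for resolving resistance
changes. In practice instrument builders often choose a much smaller load
(around $R_p/15$) to place the output voltage conveniently within the DAQ
range; the package exposes the sensitivity function so users can evaluate
both operating points, and takes no position on the trade-off.

## Synthetic recording model

`generate_recording()` draws, for channel $s$ with baseline $b_s$:

$$x_s(t) = b_s\,\bigl(1 + A_s (1 - e^{-t/\tau_s})\bigr)
  + \delta\,t + \beta_s\,\eta_s(t) + \varepsilon_s(t), \qquad t = 0..N-1$$

* **Saturating exponential rise** $1 - e^{-t/\tau}$: real MOS transients show
  a fast rise to a steady plateau; the exponential is the simplest shape with
  a controllable frequency signature, so both the amplitude $A_s$ (driving
  AV) and the time constant $\tau_s$ (driving MV) can carry class
  information independently.
* **Baseline** $b_s$: log-uniform in `baseline_range` (default 1–3 V), drawn
  once per recording. The relative-difference transform divides by the
  baseline, so the distribution is bounded away from zero by construction.
* **Drift** $\delta t$: additive and linear (default `2e-6` V/sample, about
  1% of baseline over a full recording). Long-term zero-value drift has no
  agreed functional form; linear is the minimal model that the
  relative-difference transform partially suppresses.
* **Band-limited fluctuation** $\beta_s \eta_s(t)$: unit-variance white noise
  smoothed by a circular 25-sample moving average. Its power concentrates in
  the low-frequency wavelet leaves, giving the MV features a second,
  amplitude-independent class signal when $\beta_s$ is class dependent.
* **White noise** $\varepsilon_s(t)$: measurement noise, default sd 0.01 V.
* **Response jitter** (`response_jitter_sd`): a per-recording multiplicative
  log-normal jitter on the amplitudes. It is 0 in the single-recording
  primitive (so the closed-form contracts above hold exactly) and 0.05 in
  `generate_dataset()` and the pipeline: a 5% replicate-to-replicate response
  scatter is typical repeatability for MOS arrays, and without it every
  classifier saturates at 100% from the first feature subset, which would
  make the wrapper sweep meaningless.

`make_class_profiles()` encodes the default study design: 8 classes, 16
channels of which 5 (`T2, T5, M1, M4, M7`) are informative. On an
informative channel, amplitude (0.30–0.86), rise time (200–900 samples) and
band-fluctuation sd (0.002–0.0125 V) each step through the classes in a
channel-specific cyclic order, so the informative features are not mutually
collinear; uninformative channels respond identically for every class
(amplitude 0.5, $\tau$ = 400, $\beta$ = 0.004). Keeping most channels
uninformative is deliberate: it lets tests measure whether VIP ranking
*recovers* the informative set rather than merely reproducing a fit.

**What the simulator does not model:** sensor chemistry (adsorption
kinetics, humidity/temperature cross-sensitivity), non-linear or
non-monotone drift, inter-channel correlated noise, and recovery/cleaning
transients between measurements. Passing tests therefore demonstrate that
the pipeline recovers structure *of the kind it assumes*; they do not
certify performance on any particular instrument.

## Preprocessing

`relative_difference()` computes $y_s(t) = (x_s(t) - x_s(0))/x_s(0)$ with
$x_s(0)$ taken from the recording's stored pre-injection zero value, not from
the first sample — the zero value is observed on clean air before injection
and is the quantity drift actually shifts. The transform is exactly
invariant to any multiplicative channel gain, which is the drift-suppression
contract, and it is applied per time point *before* feature extraction (the
features are then statistics of the relative signal).

Min–max scaling (`fit_scaler()` / `apply_scaler()`) maps each feature onto
$[0,1]$ using training-set extrema; test-set values outside the training
range are clipped. The open-interval "(0, 1)" convention is implemented as
the closed interval — the endpoints are attained by the extreme training
samples by construction. Constant (degenerate) features map to the midpoint
0.5: any constant works, the midpoint is the symmetric choice. By default
the scaler is fitted on the training partition only (no leakage); a
whole-table fit is available where an analysis normalizes before splitting.

## Features

Per channel, `average_value()` is the arithmetic mean of the relative signal
(AV), and `wavelet_packet_leaf_variances()` + `mean_variance()` give the MV
feature: the mean of the variances of the $2^3 = 8$ leaf coefficient
sequences of a depth-3 db6 wavelet packet decomposition.

Numerical choices:

* **Boundary mode** defaults to periodization, under which the decomposition
  is an orthogonal circular transform and Parseval's identity holds to
  machine precision on lengths divisible by $2^{depth}$ — this is the
  invariant the test suite checks. A symmetric-reflection mode is provided
  for users matching toolchains that extend by reflection; it is not energy
  preserving.
* **Odd lengths** are padded by repeating the last sample at the affected
  level (the default 5940-point signal hits an odd length at depth 3).
* **Variance** is the population variance (divide by $n$) by default, with a
  sample-variance option; since MV averages all leaves, the choice only
  rescales MV slightly and uniformly.
* **Leaf order** defaults to natural (filter-bank) order, with a
  frequency-band (Gray-code) option; MV is order invariant, so the setting
  only affects exported intermediates (`leaf_variance_table()`).
* The implementation was verified leaf-by-leaf against an independent
  wavelet library; the reference values are frozen in the test suite.

## Feature selection

**PCA** (`pca_fit()` / `pca_reduce()`): covariance-based on the centered,
already min–max-scaled table (autoscaling available). Retention is either an
explicit component count (default 10) or the smallest count reaching a
cumulative explained-variance cutoff. PCA scores are re-scaled onto $[0,1]$
before classification so the PNN spread keeps one interpretation everywhere.

**PLS-DA VIP** (`pls2_fit()` / `vip_scores()`): PLS2 by NIPALS against the
one-hot class matrix, centering only by default (the features are already on
a common $[0,1]$ scale; autoscaling is a flag). The component count defaults
to $C-1$ (7 for 8 classes), which spans the between-class subspace of the
one-hot response. VIP uses Wold's formula with
$ssy_a = \lVert q_a\rVert^2\, t_a^\top t_a$; the identity
$\sum_j VIP_j^2 = p$ is enforced as a test invariant. A VIP score above 1 is
reported as an annotation only — subset evaluation, not the threshold,
selects the model. Ranking ties break toward the earlier feature in table
order, so results are deterministic.

**Nested subsets** (`nested_subsets()`): subset $i$ holds the top-$i$ ranked
features; with 32 features this yields the 32 nested candidate models swept
by `evaluate_subsets()`.

**Kennard–Stone** (`kennard_stone()`): Euclidean max–min greedy selection,
seeded with the globally most distant pair, ties broken toward the lowest
sample index (determinism is required for reproducible splits). The split is
computed in the normalized 32-feature space; since no training set exists
before the split, the scaler for this step is fitted on all samples, and the
classification scaler is then refitted on the training partition.

## Classifiers and evaluation

**PNN** (`pnn_fit()` / `pnn_predict()`): class score
$\pi_c \cdot \mathrm{mean}_{i \in c}\, e^{-\lVert x - x_i\rVert^2 / 2\sigma^2}$,
arg-max with ties to the lowest class id. Scores are compared in the log
domain with a shared max-shift, so the $\sigma \to 0$ limit degenerates to
exact 1-nearest-neighbour labeling instead of underflowing. Default
$\sigma = 0.1$ on $[0,1]$-scaled features — about the inter-sample spacing
at which a handful of training patterns per class still overlap; priors are
uniform by default (the design is balanced: 5 training samples per class).

**Random forest** (`rf_fit()` / `rf_predict()`): delegated to the
`randomForest` package under the classical protocol — bootstrap resamples of
size $n$, unpruned Gini CART trees (`nodesize = 1`), `mtry` random candidate
features per node, majority vote, fully seeded. `mtry` defaults to
$\mathrm{round}(\sqrt{p})$ *of the feature set actually used*, i.e. 4 on
15/16-feature subsets; this per-subset reading keeps the rule meaningful
inside the nested sweep.

**Evaluation** (`evaluate_subsets()`, `tree_sweep()`): forests are averaged
over seeded repetitions (default 100, matching the repeated-model averaging
protocol; the PNN is deterministic so one run suffices). The tree sweep
covers 2–100 trees in steps of two and reports a stabilization point: the
smallest count from which all later mean test accuracies stay within a
5-point band of the final value. Arg-max ties in the subset sweep go to the
smaller subset (parsimony).

## Problem sizes in the shipped tests

Unit tests run on 16-channel arrays of 64–256 timepoints and 3–12 samples —
large enough to exercise every invariant, small enough to keep the suite
fast. The end-to-end checks run the full study geometry (80 recordings of
16 × 5940) with 10-repeat forest averaging and a 20-replicate recovery
study; these sizes are the package's chosen compromise between statistical
resolution and a test suite that completes in minutes on one CPU. The
pipeline default remains 100-repeat averaging.

## Known limitations

* The simulator's class structure is cyclic and low-dimensional by design;
  real liquor fingerprints are messier, and the recovery rates measured on
  synthetic data are upper bounds, not field estimates.
* Only two wavelet families (db6, Haar) are built in.
* The PLS component count is fixed, not cross-validated; sparse or
  orthogonal PLS variants are out of scope.
* Online/adaptive drift compensation is out of scope: the package implements
  the offline relative-difference approach only.
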