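---
title: "Decoding stimulus categories from functional-connectivity patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding stimulus categories from functional-connectivity patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcdecoder)
```

## The analysis in one paragraph

fcdecoder implements multivariate pattern analysis on *functional
connectivity* (FC): instead of asking which brain regions activate for a
stimulus class, it asks whether the pattern of pairwise temporal
correlations between regions carries class information. ROI time series
from a block-design fMRI experiment are denoised (CompCor-style nuisance
regression plus 0.01–0.1 Hz band-pass), cut into condition-specific
volume sets by a hemodynamically shifted boxcar, and correlated region
by region. Each subject then contributes one Fisher-z edge vector per
class. Group-level one-sample t-tests with Benjamini–Hochberg FDR
(q = 0.01) define the significantly *positive* edges per class; their
union per condition is the feature space. A leave-one-subject-out
cross-validation (LOOCV) loop selects features fold-internally by
one-way ANOVA (p < 0.05 on training subjects only), trains a one-vs-one
linear SVM ensemble — C(6, 2) = 15 binary classifiers, majority vote —
and evaluates accuracy on all held-out samples. Significance comes from
a permutation test that reruns the *entire* cross-validation (feature
selection included) under shuffled class labels. Edges selected in every
fold ("consensus features") form the discriminative network.

## The experimental design being modeled

The timing model reproduces a 4-run block design with six expression
classes crossed with three presentation conditions (static, dynamic,
obscured; the obscured condition is scheduled but not analyzed). Each
run presents the 18 expression-by-condition blocks once, in a
pseudo-random order with no two consecutive blocks sharing an expression
or a condition; each block holds 12 stimuli of 1.52 s with a 0.48 s ISI
(24 s), preceded by 10 s fixation and followed by a 4 s button task.
That yields 18 x 38 s = 684 s (11.4 min) per run and 45.6 min per
experiment, at TR = 2 s, with the first five volumes of each run
discarded. These numbers are asserted exactly in the test suite.

The pseudo-random order is drawn by seeded random sequential
construction (pick each next block uniformly among those not repeating
the previous expression or condition) with rejection of dead ends, under
a retry cap. Plain rejection over full permutations is infeasible here:
with three conditions filling six slots each, only about 1 in 20,000
permutations satisfies the adjacency constraint.

### Volume selection

Volume k (0-based) covers [kTR, (k+1)TR); a volume belongs to a block if
its midpoint, shifted back by `hemodynamic_shift_s` (default 4 s, two
TRs), falls inside the block. The shift is a coarse surrogate for the
BOLD delay; the toolbox pipelines this emulates use HRF-weighted GLMs
whose exact weighting is not public, so the boxcar is a documented
approximation, not a claim about those internals. With the default
design each expression x condition yields 12 volumes per run, hence 48
per subject after cross-run concatenation — correlation is computed on
the concatenation rather than averaged per run, to maximize the volumes
entering each estimate.

## The synthetic cohort

No imaging data ship with the package; a generator emulates the cohort
so every stage is testable, with recorded ground truth for
parameter-recovery tests.

Signal is planted *at the edge level*, because edges are what the
pipeline decodes: a base correlation matrix is built from a random
low-rank factor model, and each class raises its own disjoint set of
`n_signal_edges_per_class` (60) edges by `class_effect_size` (0.3) in
Fisher-z space, followed by projection back to the nearest
positive-definite correlation matrix. Latent neural vectors are drawn
volume-wise from the active block's class covariance (base covariance
during fixation), convolved per ROI with a double-gamma HRF, and
overlaid with subject-level edge jitter, slow WM/CSF-like nuisance
signals, motion-correlated drifts, and white noise.

Parameter choices that the package fixes, with rationale:

* **Base factor loadings N(0.13, 0.20), R/8 factors.** Calibrated so
  that at 18 subjects and q = 0.01 roughly a quarter to a third of the
  6216 edges test significantly positive per class and about half pool
  across classes — the prevalence regime the positive-edge selection
  step is designed for. Acceptance runs land near 2900–3300 pooled
  features.
* **`subject_noise_sd = 0.1`** (z units): between-subject connectome
  variability, the noise that across-subject decoding must overcome.
* **`white_noise_sd = 0.5`**: volume-wise noise at half the latent
  signal SD; after band-pass filtering this leaves a realistic fraction
  of non-neural variance.
* **`motion_amplitude = 0.2`**, ten nuisance signals: enough structure
  for CompCor and motion regression to have real work to do.

What the generator does **not** emulate: spatial structure (ROIs have no
geometry), scanner artifacts beyond linear-mixture nuisance, non-neural
physiological rhythms, hemodynamic variability across regions, and any
perceptual specifics of the obscured-eyes condition (generated only so
schedules match the design). Passing recovery tests therefore
demonstrates that the *pipeline* recovers edge-level class structure
under realistic noise — not that real cortex behaves like the generator.

An important attenuation is deliberate and physical: HRF convolution
mixes latent activity across block boundaries, so of a nominal planted
effect of 0.3 z only about 0.13–0.16 survives into the estimated
condition FC even noise-free. Recovery tests operate on the realized,
not nominal, effect.

## Denoising

Nuisance principal components (top 5 left singular vectors of the
standardized nuisance table), six motion parameters and a linear trend
are regressed out per run; the residuals are band-pass filtered at
0.01–0.1 Hz with a zero-phase FFT mask. Regression precedes filtering
(the emulated toolbox also offers simultaneous regression-plus-filter;
the sequential order is simpler and documented). The filter's
transition-band width defaults to 0.001 Hz — at typical run lengths this
is below one frequency bin, so band edges are effectively sharp, the
pass band has unit gain, and applying the full denoise pass twice
changes the output by well under 1% RMS. Filtering is applied per run,
after the initial-volume discard and before concatenation, to avoid
cross-run edge artifacts. The block fundamental (1/38 s = 0.026 Hz) sits
comfortably inside the pass band.

## Group statistics and the feature space

For each expression x condition, edges are tested across subjects with a
one-sample t-test (df = 17 at the default cohort size) and adjusted by
Benjamini–Hochberg within that cell's 6216 edges (the family is the
cell, not the pooled set). "Significantly positive" is implemented as
*two-sided* adjusted p <= q combined with t > 0 — the common toolbox
behavior — rather than a one-sided test; the package states this
explicitly because the two readings differ. The second-level group
network uses the same machinery at adjusted p < 0.001, two-sided, sign
retained; the threshold applies to the adjusted p.

## Decoding

Within each LOOCV fold the ANOVA filter sees training subjects only —
the test suite asserts this structurally (each fold's selected set
equals an independent re-selection from training rows alone) and
statistically (a deliberately leaky variant kept only in the tests,
which selects on all subjects, inflates null-data accuracy from ~0.17 to
~0.6, demonstrating that the guard matters). Features are standardized
per fold with training means and SDs because margin classifiers are
scale-sensitive. Binary SVMs are linear with C = 1 (the emulated study
does not state its constant); the one-vs-one vote is tallied over 15
classifiers, and vote ties are broken by the largest summed signed
margin, with a lowest-index rule available. A fold that selects zero
features falls back to the full pooled feature space and is logged.

The permutation test shuffles labels *within subject* by default,
preserving subject exchangeability (a global shuffle is available), and
reports p as the plain count fraction `#(null >= observed) / N` — the
convention of the emulated analysis, which can return exactly 0; a
`(b + 1) / (N + 1)` smoothed estimator is available as an option.

Two statistical facts about this design, established empirically in the
acceptance tests and worth knowing when reading results:

* LOOCV accuracies under the null are *overdispersed* relative to
  Binomial(108, 1/6): the 108 predictions are dependent (six per
  held-out subject, strongly overlapping training sets). The observed
  replicate SD is about 1.5x binomial. Chance-level assertions are
  therefore made on accuracy pooled over replicate cohorts; a single
  run's accuracy should be judged by its own permutation p, never by a
  binomial interval.
* The permutation p is close to uniform under the null (empirical size
  near 0.05 at the 0.05 level over replicate null cohorts), which is
  exactly what licenses it as the significance measure.

## Consensus networks

Edges selected in every fold form the expression-discriminative network;
node degrees count incident consensus edges per ROI. The packaged
112-row atlas table supplies labels (a constructed Harvard–Oxford-style
stand-in, see `inst/extdata/roi_labels_112_synthetic.tsv`) and MNI
coordinates for the nodes shared by the static and dynamic
discriminative networks (packaged coordinate table). On planted-signal
cohorts the consensus network's overlap with planted edges is tested
against the hypergeometric 95% null quantile.

## Problem sizes used by the tests and the acceptance script

The test suite runs the full default cohort (18 subjects, 112 ROIs,
4 runs) for signal recovery with 100 permutations on one condition, and
twenty 18-subject, 20-ROI null cohorts with 100 permutations each for
calibration; the end-to-end determinism check uses a 6-subject, 20-ROI,
50-permutation smoke configuration. The acceptance script analyses one
default cohort with 199 permutations per condition. These sizes are the
package's chosen trade-off between statistical resolution and a test
suite that runs in minutes; all of them are parameters, not constants.

## Known limitations

* The shifted-boxcar condition mask is a surrogate for HRF-weighted
  condition estimation; near-boundary volumes are mixtures.
* The pooled positive-edge space is built on all subjects before LOOCV,
  reproducing the emulated analysis faithfully at the cost of a mild
  circularity (the feature *space* — not the fold-internal selection —
  sees the test subject). `decoding_spec(nested_positivity = TRUE)`
  recomputes the positivity masks within each training fold instead;
  the faithful variant remains the default.
* Correlation-based FC only: no partial correlation, tangent-space or
  GLM-based connectivity.
* The behavioral generator is independent of the fMRI generator, as the
  two analyses are independent; no stimulus-level psychometrics are
  modeled.
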