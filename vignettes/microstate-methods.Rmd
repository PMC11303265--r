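---
title: "EEG microstate analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG microstate analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Resting-state EEG is modelled as a sequence of *microstates*: quasi-stable
scalp potential topographies, each lasting tens of milliseconds, drawn
from a small inventory of template maps (canonically four classes, A-D).
The analysis pipeline in `microstatr` follows the classical peak-based
formulation:

1. **Global field power (GFP).** At each time point the spatial standard
   deviation across channels (population form, denominator = channel
   count) summarises field strength. Local GFP maxima are the moments of
   highest topographic signal-to-noise, so only the topographies at GFP
   peaks enter clustering.
2. **AAHC clustering.** Atomize-and-agglomerate hierarchical clustering
   starts from every peak map as a singleton cluster and repeatedly
   dissolves the cluster contributing least to the global explained
   variance (GEV), reassigning each orphan to the cluster whose centroid
   it correlates with most strongly *in absolute value*. Polarity is
   ignored throughout: a map and its negation are the same microstate.
   Centroids are the first principal component of the member maps, the
   polarity-invariant analogue of the mean. Exactly `n - k` atomization
   rounds yield `k` templates.
3. **Two-level templates.** Subject-level templates are clustered a
   second time across subjects to produce group templates, which are
   labeled A-D by an optimal assignment against analytic reference maps
   (two mirror-symmetric oblique gradients, one curved
   anterior-posterior pattern, one central radial map, symmetrically
   orthogonalised on the working montage).
4. **Backfitting and statistics.** Each sample is labeled with the
   template of maximal absolute spatial correlation; GEV quantifies how
   much GFP-weighted variance the labeling explains. From the label
   sequence come the four dynamic parameter families: per-class mean
   duration (ms), time coverage (%), occurrence (/s) and the 12 ordered
   transition probabilities.

The statistical layer mirrors common clinical practice: Shapiro-Wilk
gated two-group tests (pooled-variance t when both groups pass at
alpha = 0.05, Mann-Whitney otherwise; Pearson chi-squared without
continuity correction for sex), mixed Group x Class ANOVA (between x
within) with Greenhouse-Geisser correction when Mauchly's test rejects,
Bonferroni post hoc tests with the "> 0.9999" display cap, and Spearman
correlations between clinical measures and microstate features. The
diagnostic layer is a linear SVM over microstate + demographic features
evaluated by nested leave-one-out cross-validation (inner fivefold cost
search by balanced accuracy), with sequential backward feature
selection and a label-permutation test, `p = (b + 1) / (n_perm + 1)`.

## The synthetic generator

Because no public recordings accompany this problem, every stage is
validated against a generator with known ground truth:

* **State sequence.** A semi-Markov chain: successor states follow a
  conditional transition matrix (zero diagonal, rows summing to 1);
  dwell times are gamma with shape 4 (coefficient of variation 0.5,
  matching the duration SD/mean ratios of published group tables), with
  a geometric option for Markov-exact tests.
* **Topographies.** Each sample is `envelope(t) * template(state)` plus
  spatially white Gaussian noise. The envelope is a rectified 10-Hz
  sinusoid (alpha-like) with a 10% floor, so GFP exhibits ~20 peaks/s as
  the peak-based method requires. SNR is defined as
  RMS(signal)/RMS(noise) over the whole recording; the output is
  average-referenced at every sample.
* **Cohort.** Per-subject generating parameters (per-class duration and
  occurrence, 12 joint transition probabilities) are truncated-normal
  draws around group-level reference values in which the patient group
  has higher class-C occurrence/coverage, fewer A-B and A-D transitions
  and more A-to-C / B-to-C transitions. Coverage is derived as
  `occurrence x duration / 10`, renormalised to 100%. Clinical scores
  are truncated normals at published medians/IQRs (questionnaire totals
  only; item-level scoring is out of scope), with configurable
  Gaussian-copula-style couplings: vertigo symptom load anti-correlates
  with A-B transitions (rho -0.45); somatosensory-challenge equilibrium
  and strategy scores correlate positively with class-C dynamics
  (rho 0.36-0.40). Hearing (PTA) is deliberately uncoupled: no
  association is reported in the literature this emulates, so its
  default coupling is zero.

What the generator does *not* emulate: forward-modelled head geometry,
spatially correlated sensor noise, artifacts (blinks, ECG, muscle),
non-stationary alpha power, or any eyes-open condition. Passing
recovery tests therefore demonstrates the correctness of the estimators
under the stated model, not their robustness to real-world artifacts.
In the features-only cohort mode the drawn generating parameters are
emitted directly as subject features; occurrence, duration and
transitions are drawn independently there, whereas in a semi-Markov
realisation occurrence is determined by durations and the transition
matrix - the EEG mode is therefore the self-consistent one, the
features mode the fast one for statistics and classifier work.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| Broad conditioning band | 0.5-200 Hz | wide acquisition band before resampling |
| Analysis band | 2-20 Hz | the topographic band microstate work uses |
| Filter | Butterworth order 4, forward-backward | zero phase; >= 20 dB one octave out |
| Target rate | 500 Hz | 2-ms resolution, cheap downstream |
| Segment length | 2 s | statistics never bridge segments |
| k (classes) | 4 | the canonical inventory; still a parameter |
| GFP peak separation | 10 ms | merges jittered double peaks; 0 = pure maxima |
| Backfit mode | per-sample argmax | `peak_interp` available for sensitivity |
| Min-duration smoothing | 12 ms | see below |
| SVM cost grid | 0.001..100 (decades) | standard span for linear SVM |
| Dwell shape | gamma, shape 4 | CV 0.5 as in group tables |
| SNR | 4 | moderate; recovery still near-perfect |

## Numerical choices and degenerate inputs

* **Polarity.** All clustering/backfitting correlations use absolute
  values; centroid signs are fixed deterministically (positive
  correlation with the first member), and canonical labeling re-orients
  maps to correlate positively with their reference.
* **Ties.** Exact backfit ties go to the lowest canonical label;
  AAHC's worst-cluster ties to the lowest cluster index; equal-cost
  grid points to the smallest C; tied feature removals to the smaller
  absolute SVM weight. All deterministic.
* **Zero-variance samples** cannot be correlated; they inherit the
  nearest labeled sample's label within their segment and contribute
  correlation 0 to GEV. Zero-variance maps are rejected outright.
* **Truncated runs.** Runs touching a segment edge are excluded from
  mean duration (their dwell is censored), included in coverage (time
  spent is time spent) and counted for occurrence only when their onset
  is observed. Transitions never cross segment boundaries.
* **Transition normalisation** is joint (the 12 ordered pairs sum
  to 1); published group tables of this quantity sum to ~1, supporting
  the convention. A row-conditional accessor
  (`conditional_transition_matrix`) inverts it for generator
  comparisons.
* **Staging** rounds half-up to integer dB before applying the integer
  stage bands, resolving values inside the printed gap (25, 26).
* **Composite equilibrium score**: the exact weighting is not published
  with full precision in clinical sources; the standard protocol
  weights (1, 1, 3, 3, 3, 3)/14 are the default and are configurable.

## Why the pipeline smooths backfit labels (12 ms)

The backfit operation itself performs no temporal smoothing by default:
per-sample argmax labeling is the cleanest definition and remains
available untouched. The subject-level *pipeline*, however, enables
12-ms minimum-duration smoothing by default, for a physical reason. At
a recording-level SNR of 4, instantaneous SNR at envelope troughs drops
below 1, so a handful of samples near each trough are labeled at
chance. Those blips fragment runs: in a 600-s pilot, raw per-sample
labeling underestimated mean durations by ~11 ms and overestimated
occurrence by ~0.8/s, while the peak-interpolation alternative
overshot durations by 5-7 ms (short runs containing no GFP peak are
invisible to it). Reassigning runs shorter than 12 ms (6 samples at
500 Hz) to the better-correlating neighbouring run removes the blips
without touching genuine dwells - 12 ms sits below the 1st percentile
of the gamma dwell law at the durations this field reports - and
recovers durations to < 1 ms, occurrence to < 0.1/s and joint
transitions to < 0.002. Larger thresholds (>= 20 ms) begin to prune
real runs and bias occurrence downward.

## Problem sizes used by the test-bench

The bundled tests and the acceptance script size their simulations for
a desk-scale single-CPU run: one 600-s, 32-channel recovery recording
(the long-run benchmark for template, label, duration, occurrence and
transition recovery); cohorts of 32/29 subjects in features mode for
statistics and classification (20 seeds for the accuracy-stability
check); 100-200 replicate calibrations for null distributions; and
exhaustive partition oracles up to 8 maps. These sizes are the
package's own choices for a reproducible benchmark.

## Leave-one-out pathologies and the degeneracy guard

Leave-one-out validation interacts badly with two classifier regimes,
both of which matter for honest permutation calibration:

* **Majority-flip.** A heavily regularized (small-C) linear SVM
  degenerates into a majority voter, and in LOOCV the held-out subject's
  class is always the training minority -- so a degenerate model is
  wrong (far) more often than chance, dragging permuted-label balanced
  accuracy well below 50%. The pipeline therefore refuses to deploy a
  cost whose fitted model predicts a single class on its own training
  data, falling back to the next-best cost from the inner search. With
  this guard, permuted-label balanced accuracy averages ~50% as a null
  calibration requires. (Inverse-frequency class weights were evaluated
  as an alternative and rejected: they overcompensate, tilting
  predictions toward the held-out class and pushing the null *above*
  chance.)
* **High-dimensional anti-learning.** When the feature count approaches
  the training size (p ~ n), an interpolating fit anti-correlates with
  the held-out subject even under permuted labels, biasing LOOCV below
  chance regardless of the guard. Null calibrations are therefore run
  with feature sets well below n; with the full 24-feature microstate
  set plus demographics this artifact is visible at small n and shrinks
  with cohort size. The permutation *test* remains valid either way --
  observed and permuted scores share the bias -- but raw permuted-label
  accuracy is only interpretable as "chance = 50%" when p << n.

## Known limitations

* Greedy AAHC is not guaranteed globally optimal; it provably matches
  the exhaustive best-GEV partition on the small well-separated
  instances tested, and empirically recovers generating templates at
  |corr| > 0.999 on long recordings, but clustering quality degrades on
  very short recordings (tens of seconds), where a low-occupancy class
  can be absorbed before the target cluster count is reached.
* The permutation test's fast mode freezes the selected features and
  cost from the observed run; it is anti-conservative with respect to
  the selection step and exists for budget-constrained calibration.
  Full-pipeline permutation is the exchangeable (default-correct) mode.
* ICA artifact removal is a pass-through hook accepting an external
  unmixing; no automated component scoring is provided.
* Only a documented plain-text container is read/written; binary EEG
  formats are outside this package's scope.
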