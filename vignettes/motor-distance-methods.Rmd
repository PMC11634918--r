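---
title: "Motor distance from Procrustes-aligned movement repertoires: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motor distance from Procrustes-aligned movement repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motordist)
library(ggplot2)
```

## The problem

People have recognizable, relatively stable ways of moving — a *motor
style*. Quantifying how far apart two individuals' styles are (a *motor
distance*) requires comparing whole movement repertoires, not single
trials, and doing so in a way that is insensitive to nuisance differences
in overall amplitude, duration, and orientation while staying sensitive to
the *shape* of the movement.

`motordist` operationalizes motor distance for reach-to-grasp movements.
Each trial is reduced to three scalar kinematic series — wrist velocity
(WV, the module of the velocity vector, mm/s), wrist acceleration (WA, the
rate of change of WV, mm/s²) and wrist jerk (WJ, the rate of change of the
module of the acceleration vector, mm/s³) — time-normalized into 10
deciles, giving a 10 × 3 matrix per trial. Viewed as 10 landmarks in the
WV–WA–WJ space, each trial is a *shape*, and shape analysis supplies a
principled dissimilarity: the normalized Procrustes distance.

## The Procrustes core

Given a target matrix $X$ and a comparison matrix $Y$ (both $n \times k$),
both are centered and scaled to unit centered Frobenius norm, and the
optimal rotation/reflection comes from the SVD of the cross-product of the
normalized matrices, $X_0^\top Y_0 = U \Sigma V^\top$, with
$T = V U^\top$. With scaling enabled the residual after the optimal
similarity transform is

$$ d = 1 - \left( \sum_i \sigma_i \right)^2, $$

the residual sum of squares standardized by the target's centered sum of
squares. This standardization is what bounds $d$ in $[0, 1]$ and makes it
symmetric in its arguments; `procrustes_distance()` asserts the symmetry to
1e-12 and averages the two directions. Translation, rotation, reflection
and scaling are all removed — rotation is included even though one might
list only "translation, scaling, and reflection", because the standard
least-squares Procrustes solution optimizes over the full similarity
group, and the orthogonal factor $T$ covers rotations and reflections
jointly. Degenerate shapes (all landmarks identical) are rejected with an
error rather than assigned a conventional distance: they cannot arise from
real movement and indicate an upstream bug.

`procrustes_fit()` is validated two independent ways in the test suite:
against a brute-force minimizer over the planar similarity group (angle
grid plus golden-section refinement, closed-form optimal scale) on 2-D
shapes, and against vegan's symmetric Procrustes statistic.

## Preprocessing choices

* **Filtering.** Positions are low-pass filtered per axis with a 2nd-order
  Butterworth at 8 Hz (default), applied forward and backward for zero
  phase (effective 4th order; the magnitude response is squared). The
  implementation uses steady-state initial conditions plus odd-reflection
  edge padding, so a constant input passes through exactly and edge
  transients do not leak into the movement window. Filtering precedes
  differentiation: derivatives amplify any residual noise, so smoothing
  the trajectory once is both standard biomechanics practice and the
  numerically safer order.
* **Derivatives** use central differences on interior samples and
  one-sided differences at the endpoints, with `dt = 1/sample_rate`:
  second-order accuracy without additional smoothing.
* **WA's sign.** "Rate of change of wrist velocity" can be read as
  $d\,\mathrm{WV}/dt$ (signed) or as the module of the acceleration vector
  (non-negative). The default is the signed reading, which keeps
  deceleration visible; `wa_method = "dnorm"` switches to the module. WJ
  is always the rate of change of the acceleration module.
* **Decile bins** for a series of length $N$ are the half-open index
  ranges $[\lfloor (b-1)N/10 \rfloor, \lfloor bN/10 \rfloor)$ (0-based):
  deterministic, non-overlapping, and exhaustive for any $N \ge 10$.
* **Windowing** is the caller's job: input trials are assumed to run from
  reach onset to offset. No onset detection is performed.

## Inter-trial alignment (FPT trials)

A subject's $t$ trials are collapsed into one representative by fixing a
target trial (by default the first available one), Procrustes-fitting each
remaining trial onto it, and averaging the $10 \times 3 \times t$ stack
elementwise. The target itself enters the stack untransformed, so $t$
matches the retained-trial count. Per-cell standard deviations across the
stack record inter-trial variability; the population (divide-by-$t$)
convention is used because the stack is the complete set of retained
trials, with a `sd_type = "sample"` flag available. Alignment is one-pass:
trials are not re-fitted to the evolving mean (no generalized-Procrustes
iteration), reproducing the published procedure as described.

Because the target choice is arbitrary, `target_sensitivity()` reruns the
whole pipeline under alternative target rules and reports pairwise Mantel
correlations between the resulting distance matrices.

## The statistical machinery

* **Swap test.** The observed statistic is the mean of the
  confederate–confederate (within-person) block. Each of the 1000 default
  permutations substitutes a random within-person cell $(i, j)$ with the
  distance from the *same* confederate instance $i$ to a random
  participant and recomputes the mean; $p$ is the fraction of permutations
  that *strictly* reduce it (ties conservatively do not count). Cells are
  drawn independently per iteration. Because one substitution shifts the
  block mean by exactly $(\text{new} - \text{old})/m$, the test is
  computed in O(n_perm) without re-averaging; the identity is verified
  against the naive recomputation in the tests.
* **MDS.** Classical scaling (principal coordinates of the double-centered
  squared distances) initializes an iterative metric-stress majorization
  (SMACOF, unweighted Guttman transform), with Kruskal stress-1
  $\sqrt{\sum (\delta_{ij} - \hat d_{ij})^2 / \sum \delta_{ij}^2}$
  reported over the upper triangle. Majorization guarantees a monotone
  non-increasing stress trace (asserted per step in the tests);
  convergence is declared when the per-step decrease falls below 1e-6,
  capped at 300 steps.
* **ICC robustness.** For removal fractions 10%–80% (step 10%), trials are
  dropped uniformly at random per subject (each subject keeps at least 2),
  the alignment + distance pipeline is rerun, the per-fraction matrices
  are averaged over iterations, and ICC(A,1) — two-way, single
  measurement, absolute agreement, $(MS_R - MS_E)/(MS_R + (k-1)MS_E +
  \frac{k}{n}(MS_C - MS_E))$ with $k = 2$ — compares each averaged
  matrix's upper triangle with the full-data one. Absolute agreement (not
  consistency) is the right slot because a reduced dataset should
  reproduce the same distance *values*, not merely their ordering.
* **Mantel test.** Pearson correlation between upper-triangle vectors,
  null distribution from joint row/column relabellings of the second
  matrix (5000 by default), one-sided for positive association. The
  default p-value convention includes the observed statistic in the null
  set ($p \ge 1/(n_{perm}+1)$), which is the valid-p convention; a
  pure-count variant is exposed for compatibility with reports of
  $p < 1/n_{perm}$.
* **IMS baseline.** The individual-motor-signature comparison computes,
  per kinematic variable, the RMSE between subjects' FPT columns over the
  10 time points, normalizes each per-variable matrix by its maximum
  off-diagonal entry (mapping to $[0,1]$; "normalized" could also mean
  z-scoring or unit-sum — max-scaling is chosen as the reading that puts
  both methods on the same 0–1 range), and averages the three. IMS is
  computed on the same FPT representations as the Procrustes path so the
  comparison isolates the distance computation itself.
  `method_comparison()` enumerates every cell of the selected group block
  (120 upper-triangle cells for 16 within-person instances, 256 for the
  16 × 16 between-group block), substituting one IMS value at a time into
  the Procrustes matrix and counting strict reductions of the block mean.

## The synthetic generator

`simulate_trials()` emulates the study design the method targets: 16
participants plus 16 sessions of a single confederate (one shared style),
around 20 trials each, two grip conditions, 100 Hz. Each trial follows a
minimum-jerk reach $x(u) = D(10u^3 - 15u^4 + 6u^5)$ with $u = \tau^\gamma$
— the standard point-to-point model with a closed-form peak speed
$15D/(8T)$ that the tests check — plus a curvature bow in a second axis
and smooth additive noise (white noise low-passed at 6 Hz). Trials are
sampled at the exact declared rate on a midpoint grid centred in $[0, T]$,
so a symmetric speed profile is sampled palindromically.

Defaults (chosen once, as typical tabletop reach-to-grasp magnitudes):
amplitude 200–400 mm, duration 0.6–1.4 s, asymmetry exponent 0.8–1.25,
curvature 10–60 mm, 5% per-trial coefficient of variation on the style
parameters, 1.5 mm additive noise, and an 8% per-subject style
perturbation across conditions (making the PG and WHP distance structures
correlated but not identical, which is what the cross-condition Mantel
test needs). These settings place within-subject variability well below
between-subject style differences — the generative premise of the method.

What the generator does *not* emulate: marker dropout and labelling noise,
onset/offset detection error, grip-aperture/finger kinematics, motor
interference between co-acting partners, and non-minimum-jerk movement
classes. Passing tests therefore show that the pipeline recovers planted
style structure under clean, well-modelled kinematics; they do not certify
performance on raw motion-capture data with those artefacts.

## Worked example

```{r example, fig.width = 6, fig.height = 4}
trials <- simulate_trials(
  design = synth_design(n_participants = 6, n_confederate_instances = 6,
                        trials_per_instance = 8, conditions = "PG"),
  seed = 42)
fpt <- trials |> trial_matrices() |> fpt_trials()
D <- motor_distance(fpt)
glance(D)

swap_test(D, n_perm = 1000, seed = 1)
mds <- mds_embed(D)
glance(mds)
autoplot(mds)
```

The within-person (confederate–confederate) block mean sits far below the
between-person blocks, the swap test confirms it, and the MDS embedding
shows the confederate instances tightly clustered relative to the
participants.

## Numerical choices and degenerate inputs

* Distances are symmetrized by averaging the two fit directions; the
  analytic asymmetry is zero and the numerical one is asserted ≤ 1e-12.
* Degenerate (zero-variance) trial matrices, gaps in the input CSV, mixed
  conditions in one distance matrix, cutoffs at or above Nyquist, and
  series shorter than the filter padding or the bin count are all explicit
  errors, never silent repairs.
* Neighbour ranking breaks distance ties by label order; percentile
  positions use $\lceil q \cdot (n-1) \rceil$ on 1-based ranks (there is
  no universal percentile convention; this one is deterministic and hits
  ranks 11 and 21 for 31 comparators at $q = 0.33, 0.66$).
* All stochastic operations take explicit seeds, record them in their
  result objects, restore the caller's RNG state, and reproduce
  bit-for-bit given the same seed.

## Problem sizes used in validation

The packaged tests exercise the full 16 + 16 × 20-trial design for the
structure-recovery, MDS and robustness checks (robustness at 100
iterations for two removal fractions), and reduced designs (3–5 subjects
per group, 3–8 trials) elsewhere; the acceptance script runs the complete
pipeline on the default design with 50 robustness iterations per fraction
across all eight fractions and 5000 Mantel permutations. At these sizes
the Monte-Carlo error of the reported p-values is well below the decision
thresholds they are compared against.

## Known limitations

* One-pass alignment to a single target trial (not a generalized
  Procrustes consensus); the target-sensitivity analysis quantifies, but
  does not remove, the residual dependence.
* The 10-point time normalization discards duration information by design;
  movements differing mainly in tempo appear similar.
* ICC robustness treats the averaged subsampled matrix, not the
  distribution of per-iteration matrices; dispersion across iterations is
  available in `mean_matrices` but not summarized.
* The IMS baseline is reimplemented from its core definition (per-variable
  RMSE, normalized, averaged) on FPT representations, not the full
  original velocity-signature pipeline.
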