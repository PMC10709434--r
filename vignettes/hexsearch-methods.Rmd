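---
title: "Methods: egocentric and grid-like coding analyses for mental search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: egocentric and grid-like coding analyses for mental search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hexsearch)
```

## The problem

When people search for a goal that lives in an abstract feature space --
here, a molecule defined by the lengths of its upper and lower bonds --
the brain may reuse the machinery of spatial navigation: egocentric codes
for where the goal lies relative to the current direction of "movement"
through the space, allocentric map-like codes for the space itself, and
grid-like (hexadirectional, 60-degree-periodic) signals tied to movement
direction. `hexsearch` implements the full analysis pipeline for a
two-context recall task probing these codes with fMRI, together with a
synthetic-data generator that plants each code with known ground truth, so
that every analysis can be validated end to end against what was planted.

## Task geometry and the trial generator

The feature space is the unit square; axis 1 (x) is the upper-bond length,
axis 2 (y) the lower-bond length. Quadrants are delimited by the axis
midlines with Q1 = (low x, low y), Q2 = (high x, low y), Q3 = (low x,
high y), Q4 = (high x, high y). Each colour context hides one goal; the
blue goal (long upper, short lower bond) lies in Q2 and the green goal in
Q3, and the two are images of each other under a 180-degree rotation of
the space about its centre. The goal coordinates are a package convention
(the task defines only their quadrants): we place them at the quadrant
centres, blue (0.75, 0.25) and green (0.25, 0.75), which makes the
rotation correspondence exact and leaves Q1/Q4 equidistant from both
goals.

Each trial shows a configuration that morphs along a straight trajectory
(heading) for about 1 s and is then imagined onward for 4 s. The signed
egocentric condition is the wrapped difference between the bearing from
the start point to the goal and the heading; positive angles put the goal
counter-clockwise ("left") of the trajectory -- the side labels are
arbitrary and only the grouping matters. A run has 48 trials: 12 on-target
(condition 0) and 6 for each of -135, -90, -45, +45, +90, +135 degrees;
12 trials per quadrant; 24 target questions (6 expected "yes") and 24
filler questions whose probe lies on the trajectory 8 times and off it by
-60/+60 degrees 8 + 8 times (a 34/33/33 split rounded within run). No
morph segment crosses a quadrant boundary. Start points are sampled
uniformly in the quadrant shrunk by a 0.05 margin, at least 0.12 space
units from the goal (0.20 for on-target trials so the visible morph,
0.15 units long, never reaches it). Sessions have 8 runs, 4 per context
in random order, and whole sessions are resampled until the pooled
correlation between signed condition and start-to-goal distance is at
most 0.03 in magnitude, so distance cannot stand in for goal angle in any
analysis.

Unstated quantities fixed as conventions: inter-trial jitter uniform on
2--6 s; question window 2.5 s; allocentric directions binned into twelve
30-degree bins with ties (15 degrees mod 30) broken toward the lower bin,
and the generator avoids headings exactly on bin edges. The generator
does not balance direction bins (only conditions and quadrants); a run
typically misses one of the 12 bins now and then, so direction patterns
are averaged over the runs in which each bin occurs.

## Synthetic BOLD with planted codes

`planted_code()` realises three independent codes in a
`n_voxels`-dimensional region (default 200 voxels, a deliberately small
region that keeps full-cohort simulations fast while leaving multivoxel
analyses well-posed):

* **Egocentric tuning with adaptation.** Each voxel has a preferred
  condition and a von-Mises-shaped tuning curve (concentration
  `ego_kappa = 2` over the angular distance). The ego response is scaled
  by `1 + adapt_k * log(dt)`, `dt` the seconds since the same condition
  last appeared in the run -- the exact multiplicative counterpart of the
  analysis's log-recency modulator. First presentations carry factor 1.
* **Quadrant patterns.** One random pattern per quadrant; in the default
  `rotation` mode the green-context pattern of a quadrant equals the blue
  pattern of its rotation image (Q1<->Q4, Q2<->Q3), plus an independent
  context-specific component. `identity` mode shares patterns between
  same-named quadrants instead and serves as the negative control.
* **Grid-like direction code.** A phase in [0, 60) shared across contexts
  and a per-voxel weight map. In `rsa_tuning` mode every trial adds
  `gain * w_v * cos(n_fold (direction - phase))`; in
  `repetition_suppression` mode it adds a release-from-suppression term
  proportional to the direction change from the previous trial measured
  in 60-degree rotational space. The gain may differ between quadrants
  close to, medium-distant from, and far from the context's goal, which
  is what the goal-modulation analysis estimates.

Trial amplitudes drive boxcars over the imagination periods, convolved
with the canonical double-gamma HRF and sampled at TR = 1.5 s; AR(1)
noise (innovation sd 1, coefficient 0.3), a slow cosine drift, and a
log-normal subject-level effect multiplier (sd 0.3) complete the model.
Everything is seeded; two calls with the same seed are identical.

Default effect sizes were calibrated once so that 40-subject cohorts
detect each planted effect essentially always while group-level scores
stay modest (cross-context decoding tens of percent above chance, grid
model correlations well below 1). They are intentionally stronger than
the published group effects, which sit near the detection threshold at
this sample size: the recovery suite is meant to verify the pipeline's
correctness, not to reproduce empirical effect sizes. The gaze simulator
is the exception, calibrated so the group-mean horizontal
gaze-vs-goal-angle correlation lands near 0.02 and the choice-validation
correlation near 0.03, matching the scale of the reported estimates.

What the simulator does not emulate: spatial voxel structure (no
smoothness, anatomy or eyeball voxels -- gaze traces model the *output*
of an eyeball decoder), physiological noise beyond AR(1) + drift,
behavioural condition effects (responses depend only on the expected
answer), and any coupling between codes. Passing tests therefore show
that the analyses recover what they model from data of this structure,
not that real data behave this way.

## GLM engine

Designs are built at 10x TR oversampling. Since every regressor is an
event boxcar, the discrete convolution with the HRF kernel is evaluated
exactly as a difference of the kernel's cumulative sum at the volume
sampling times -- numerically identical to FFT convolution of the
oversampled stick functions, and fast. Parametric modulators are the same
boxcars with heights equal to the mean-centred modulator values; several
modulators on one regressor are entered jointly, with no serial
orthogonalisation, so "controlling for" a covariate has its transparent
regression meaning. Events excluded from modulation (first presentations)
are modelled by their own unmodulated regressor. A response-time stick
regressor, a discrete-cosine drift basis (128 s cutoff) and an intercept
complete the design. Fitting is voxel-wise OLS via Cholesky normal
equations; no prewhitening is applied, and with AR(1) noise the
group-level (between-subject) tests carry the inference, as is standard.
Simulated runs cache their per-trial design columns, and condition-level
designs are assembled from them by linearity; the unit tests verify that
this fast path equals the reference builder.

## Analyses

* **Egocentric adaptation** (`run_adaptation_analysis`): one imagination
  regressor with a log-recency modulator per run; the region-mean
  modulator beta (positive = release from adaptation) is averaged over
  runs and tested one-sided across subjects. Variants re-filter trials
  (off-target only; left vs right by collapsing conditions to their
  sign), split contexts, or add jointly-entered covariates (start-goal
  distance; start-quadrant recency as the repeated-starting-point
  control; direction-bin recency as the head-direction-like control).
  Lags use the natural log -- the base only rescales betas -- and never
  cross run boundaries, since runs are separated in the scanner.
* **Cross-context decoding** (`run_decoding_analysis`): run-level
  patterns of the 7 conditions (4 training exemplars per class), a
  nearest-neighbour classifier under correlation distance (configurable
  to Euclidean; ties to the first exemplar), trained on one context and
  tested per run of the other, both directions averaged, chance (1/7, or
  1/6 without the on-target class) subtracted. A within-context
  leave-one-run-out scheme supports the shared-vs-specific dissociation.
  `searchlight_map()` applies any such statistic in radius-3 spheres on a
  voxel lattice; `mds_embed()` gives the classical MDS of the condition
  correlation-distance matrix, with each axis's sign fixed so its
  largest-magnitude coordinate is positive.
* **Rotation similarity** (`run_rotation_analysis`): quadrant patterns
  per context (averaged over the 4 runs; a per-run variant exists),
  correlated blue-rows against green-columns in reversed order so the
  diagonal holds rotation-matched pairs; score = mean Fisher-z on- minus
  off-diagonal. The goal-exclusion control drops the blue-goal row and
  green-goal column (the stricter all-cells pruning is available via
  `q1q4_only`, which keeps only the two goal-equidistant quadrants).
  Note the identity-planted score is about one third of the
  rotation-planted magnitude rather than its mirror image: the four
  identity-matched cells sit among twelve off-diagonal cells.
* **Grid RSA** (`run_grid_rsa`): 12-direction patterns per context,
  cross-context correlation matrix symmetrised by triangle averaging,
  diagonal removed, lower triangle correlated with the aligned /
  misaligned indicator of each n-fold model, Fisher-z transformed. On
  30-degree bins the 6-fold model classifies all 66 pairs (30 aligned,
  36 misaligned); the 5- and 7-fold control periods have no exact
  multiples among bin differences, so those models are flagged
  degenerate and score `NA` -- a limitation of binned directions that the
  package reports rather than hides.
* **Goal modulation** (`goal_modulation_analysis`): four quadrant
  regressors per run, each with a mean-centred modulator equal to the
  60-degree-space distance from the previous trial's direction (first
  trial excluded; the sign convention models release from suppression and
  is configurable). Betas map to close/medium/far classes per context
  (Q1/Q4 averaged as equidistant; averaging before or after the subject
  GLM makes no difference here and the package does it after), and the
  group contrast is close minus far, with the linear trend over
  (far, medium, close) reported alongside.
* **Gaze and behaviour** (`gaze_subject_summary`, `behavior_metrics`):
  trial displacements are read at the volume nearest each phase onset
  (the estimates exist only on the TR grid; because the morph period is
  shorter than the TR, some trials sample both onsets at the same volume
  and contribute zero displacement -- an attenuation inherent to the
  convention). The choice validation samples the pre-question baseline at
  the last volume before the question and the question-period gaze at the
  volume nearest its midpoint, which is always inside the window. Hits
  and false alarms are percentages of "yes" answers by correct answer,
  per context and question type.
* **Group inference** (`group_test`): one-sample t-test, replaced by a
  Wilcoxon signed-rank test when Shapiro-Wilk rejects normality at 0.05
  (the gate can be disabled); directional tests one-sided as in the
  original analyses. Degenerate constant samples short-circuit to p = 0
  or 1.

## Numerical choices and degenerate inputs

Correlations at |r| = 1 are clipped to 1 - 1e-6 before Fisher transforms,
with a warning. Zero-variance patterns make correlation distance an
error in the classifier and collapse to zero/maximal distance in the MDS.
A quadrant whose within-run direction distances are all equal cannot be
modulated; its run-level beta is flagged and dropped from the subject
average. Constant modulators centre to all-zero columns, which the design
builder permits (the fitter still rejects rank-deficient models).
Searchlight spheres truncated below 10 voxels at the lattice edge are
computed but flagged.

## Problem sizes

The recovery suite simulates 20 replicate cohorts of 40 subjects (8 runs
by 48 trials, 200 voxels) per scenario -- planted effects, all-zero
nulls, identity-rotation with 4-fold tuning, and ordered goal-proximity
gains -- and checks one-sided detection at alpha = 0.05 in at least 90%
of cohorts for planted effects, with null rejections inside the binomial
range of the nominal rate. These sizes are the package's chosen
operating point: large enough for group tests to be meaningful, small
enough to run on a laptop.

## Known limitations

OLS without prewhitening mildly miscalibrates first-level variances
(group inference is unaffected); the gaze convention attenuates
trial-wise displacements as noted; direction bins are not balanced by
design; the 5-/7-fold controls are degenerate on binned directions; and
planted effect sizes are calibration choices, not estimates of the
empirical effects.
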