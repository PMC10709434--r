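# hexsearch

Egocentric and grid-like coding analyses for goal-directed "mental
search" in two-dimensional feature spaces.

## What it is for

In a two-context recall task, people keep a conceptual goal in mind (a
molecule defined by the lengths of its two bonds, i.e. a point in a 2D
feature space) while watching a configuration "morph" along a straight
trajectory, and judge whether the trajectory would ever reach the goal.
The interesting neuroscience lives in four signatures of navigation-like
coding during the imagination period:

* **Egocentric adaptation** — a region coding the signed angle between
  the trajectory and the goal (0, ±45, ±90, ±135°) shows release from
  fMRI repetition suppression growing with the (log) time since the same
  angle was last presented: the BOLD model is
  `y(t) = X β`, with a parametric modulator `log Δt_condition` on the
  imagination regressor, and subjects' modulator betas tested against 0.
* **Cross-context decoding** — a nearest-neighbour classifier (1 − Pearson
  r distance) trained on the 7 angle conditions in one colour context and
  tested in the other; accuracy − chance (1/7 = 14.29%) above 0 means a
  context-invariant egocentric code.
* **Rotation similarity** — quadrant patterns of one context correlated
  with the other context's in reversed order (as if the space were
  rotated 180°); the Fisher-z on- minus off-diagonal difference is
  positive when Q1↔Q4 / Q2↔Q3 correspondence holds.
* **Grid RSA and goal modulation** — direction patterns in 30° bins,
  cross-context similarity correlated with an aligned/misaligned model at
  60° multiples (the hexadirectional signature, with 3/4/5/7/8-fold
  controls), and a repetition-suppression modulator `δ60(current, previous
  direction)` whose gain is contrasted between the goal quadrant and the
  quadrant far from the goal.

The package provides the constrained trial generator for this design, a
synthetic-BOLD module that plants each code with known ground truth
(plus gaze traces and behavioural responses), the GLM engine, all four
analysis families, gaze/behaviour metrics and group-level inference —
everything tabular goes in and out as tibbles, results have `tidy()` /
`glance()` / `autoplot()` methods.

## Worked example

```r
library(hexsearch)

cohort <- simulate_cohort(n_subjects = 6, params = sim_params(), seed = 42)
res <- analyze_cohort(cohort)

glance(res$adaptation)
#>   label               n    mean statistic        p method sided
#> 1 adaptation_both     6 0.00720      9.26 0.000123 t      greater

glance(res$decoding)$mean      # accuracy above chance, percent
#> [1] 72.3
glance(res$rotation)$mean      # Fisher-z on-off diagonal difference
#> [1] 0.466
glance(res$grid_rsa)           # per-symmetry model correlations
#>   grid_3fold 0.455 | grid_4fold 0.035 | grid_6fold 1.13 | grid_8fold 0.035

behavior_metrics(cohort$subjects[[1]]$session)
```

The adaptation mean (0.0072 signal units per log-second, p = 1.2e-4,
one-sided) is the planted release-from-adaptation recovered from the
simulated BOLD; decoding sits 72% above the 14.29% chance level because
the planted egocentric patterns are shared across contexts; the grid RSA
peaks at the planted 6-fold symmetry while the 4- and 8-fold controls
stay near zero (3-fold is mildly positive by construction: on 30° bins
its aligned pairs are a subset of the 6-fold set). With
`quad_mode = "identity"`, `ego_shared = FALSE` or zero gains, each of
these effects disappears or reverses — that dissociation logic is what
the test suite automates.

A command-line wrapper over the same pipeline lives at
`inst/scripts/hexsearch-cli.R`
(`Rscript hexsearch-cli.R all --out results/ --seed 1`).

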