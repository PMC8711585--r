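---
title: "Pitch fatigue detection: model, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pitch fatigue detection: model, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pitchfatigue)
```

## The problem and the model

A pitcher's delivery degrades measurably before performance collapses:
the arm slot drifts upward (larger elbow valgus angle `c`), the trunk
stops driving low through release (smaller trunk flexion angle `k`), and
the time between pitches `t` stretches as the pitcher paces and rests.
This package turns those three per-pitch features into a single
percent-scale fatigue index and a detected fatigue point, plus the
cross-validation machinery to tune the method's parameters.

The model is deliberately simple and fully deterministic. For a game of
`N` pitches and a fatigue interval index `α`, pitches `1..⌊αN⌋` form the
non-fatigue reference interval and the remainder the fatigue reference
interval. Per feature `m` the knots are `x_m = mean + SD` over the
non-fatigue interval and `y_m = mean + SD` over the fatigue interval.
Each feature then maps to a fatigue value `A_m ∈ [0, 1]` by a
piecewise-linear ramp between its knots — 0 on the fresh side, 1 on the
fatigued side, linear between — rising in `c` and `t`, falling in `k`.
The total index is `M_total = 100 · Σ A_m W_m` with simplex weights, and
the fatigue point `R` is the first pitch with `M_total ≥ T`.

Assumptions inherited by the whole pipeline: one pitcher per clip, a
roughly fixed camera so 2-D image-plane angles are comparable across
pitches, posture not varying systematically with pitch type, and feature
distributions that actually shift in the stated directions once fatigue
sets in. The orientation validity flags on the bounds (`y_1 > x_1`,
`x_2 > y_2`, `y_3 > x_3`) make the last assumption checkable per game.

## Coordinate and angle conventions

Keypoints are in image pixels, origin top-left, y increasing downward
(the OpenPose convention); "vertical up" is `(0, -1)` and all angle math
is written against that convention explicitly. A keypoint with
confidence below the threshold (default 0.1) is missing, and any angle
needing it is `NA` for that pitch.

Single-camera footage does not pin down a unique 3-D joint definition,
so both angles come in two selectable planar definitions and the
pipeline downstream is definition-agnostic:

* elbow: `joint_interior` (interior angle shoulder–elbow–wrist; default)
  or `arm_elevation` (upper-arm segment against the image horizontal,
  which matches the reading that a fresh arm "appears horizontal");
* trunk: `shoulder_trunk` (angle at the throwing shoulder between upper
  arm and same-side hip line; default, the shoulder–back opening angle)
  or `trunk_vertical` (mid-hip→neck axis against image vertical).

No claim is made about which definition any particular prior system
used; with the simulator both round-trip exactly, and the fatigue maps
only consume whatever scalar stream they are given.

The inter-pitch interval is attached to the *later* pitch
(`t_i = release_i − release_{i−1}`), so a detection at pitch `i` uses
only past information; pitch 1 has no interval.

## Tunable parameters

| Parameter | Units | Default | Why |
|---|---|---|---|
| `alpha` | fraction | 0.7 | fraction of the game labelled non-fatigue; 0.7 beat 0.8 in grid search on simulated outings and is the customary late-game onset point |
| `W = (W1, W2, W3)` | unitless, sum 1 | (0.7, 0.2, 0.1) | elbow angle is the dominant, least-confounded cue; interval is noisiest (mound visits, baserunners) |
| `T` | percent | 50 | half-maximal fatigue on the `M_total` scale |
| `persistence` | pitches | 1 | plain first crossing; raise to require sustained crossings under noise |
| `conf_threshold` | confidence | 0.1 | below this a keypoint is treated as undetected |
| `sd` | — | `"sample"` | n−1 denominator; per-interval counts are small (tens of pitches) |

`M_total` lives on a ×100 percent scale: with weights on the simplex the
raw weighted sum is bounded by 1, so thresholds like `T = 50` are only
meaningful as percentages. A `raw_scale` flag disables the ×100 for
anyone wanting the bare [0, 1] index.

## Numerical and edge-case choices

* **Angles.** The vector-angle core uses `atan2(|cross|, dot)` rather
  than `acos` of the normalised dot product: the acos form loses about
  half its digits near 0° and 180°, which the collinear-placement tests
  exposed directly. Coincident keypoints (zero-length vector) are a
  classed error, not `NaN`.
* **Interval split.** `⌊αN⌋` with a `1e-9` guard so products like
  `0.7 × 7 = 4.8999…` floor to the intended 4.
* **Knot boundaries.** Values exactly at a knot take the ramp branch, so
  each map is continuous: `A = 0` at the fresh knot, `1` at the fatigued
  knot.
* **Degenerate bounds.** If fatigue does not shift a feature the right
  way, the ramp has non-positive width. Default is a hard classed error
  during training (the assumption is violated and silently producing
  scores would hide it); `degenerate = "step"` instead scores values
  past `x_m` toward fatigue as 1, for exploratory use on flat games.
* **Missing features.** A pitch missing feature `m` drops `A_m` and
  renormalises the remaining weights to the original total, keeping
  `M_total` comparable across pitches with different dropout; a pitch
  missing all three has undefined `M_total` and can never be the
  crossing pitch.
* **Detection window.** `R` is searched over the whole game by default.
  Restricting the search to the first `⌊αN⌋` pitches is available
  (`search_window = "alpha"`) but not the default: it would tie the
  detector's output range to the very target (`N·α`) that the accuracy
  metric measures against, biasing the evaluation.
* **F_P pooling.** `absolute` (default) is the literal training-game
  mean of the `R_i`. A `normalized` mode (`mean(R_i / N_i) · N_val`,
  rounded) is provided for sets of games with very different lengths;
  the CV report records which was used. Training games with no crossing
  are excluded from the pool and counted; a fold is skipped only when no
  training game crosses, and the run errors only if that holds in every
  fold.
* **Accuracy.** `A_f = 1 − |F_P − N·α| / N` is reported raw by default —
  it can go negative when the prediction is off by more than `N`
  relative to the target — with a clamp-at-zero option, because a mean
  over folds containing negatives is hard to interpret.
* **Grid ties.** Deterministic tie-break: larger `α`, then lower `T`,
  then lexicographically larger weight vector.
* **Symmetric bounds.** The literal knots use mean + SD on every
  feature even though the trunk feature shifts downward; a
  `symmetric_bounds` switch (off by default) uses mean − SD for the
  trunk, the mirror-symmetric alternative, for sensitivity analysis.

## What the simulator emulates — and what it does not

`simulate_session()` draws each feature i.i.d. normal within regime:
non-fatigue before onset pitch `⌈αN⌉ + 1`, fatigue after (intervals
resampled until positive; optional logistic blending of the regime means
over a configurable ramp; independent per-feature dropout). The defaults
— elbow 95°→110° (SD 4°), trunk 100°→85° (SD 4°), interval 18 s→25 s
(SD 3 s), 100 pitches, onset fraction 0.7 — state a clearly separated,
plausible outing (regime shifts of 2.3–3.8 within-regime SDs) and are
documented as test fixtures, not biomechanical claims; no published
distributions exist for these specific image-plane features, only the
directions of change. The ground-truth record (onset index, complete
pre-dropout values, per-pitch regime) accompanies every session, and
detection experiments compare against it, never against re-derived
values.

Real data differ in ways the generator deliberately ignores:
within-game autocorrelation (pitch sequencing, innings breaks), heavy
tails and pose-estimation outliers, gradual individual onset profiles,
feature cross-correlation, and game-to-game parameter drift. A green
detection or parameter-recovery test therefore establishes that the
machinery is correct under its stated model — not that the method
attains any particular accuracy on broadcast footage.

`synthesize_frame()` places upper-body keypoints so the angle operations
return prescribed targets exactly (verified to 1e-6 before the frame is
returned); it makes no attempt at full-body biomechanical realism.

## Classifier hook

The optional learning-layer hook `train_fatigue_classifier()` fits a
binary linear margin classifier on the `(A1, A2, A3)` triple — an
L2-regularised squared-hinge model minimised with BFGS, i.e. a linear
SVM in substance, implemented directly so the package needs no external
SVM dependency. It is an auxiliary labelled-interval classifier; the
fatigue point detection itself is the deterministic threshold rule.

## Known limitations

* 2-D image-plane angles conflate true joint angles with camera
  viewpoint; cross-game comparability assumes a consistent camera.
* The bounds are estimated per game from the α-split, so `α` acts both
  as the training-label boundary and as the evaluation target; the
  cross-validation design (held-out game contributes only its pitch
  count) limits but does not remove this circularity.
* `A_f` measures distance to the *conventional* target `N·α`, not to a
  physiological ground truth; on real data the target itself is a
  modelling choice.
* Pitch events (release/apex times) are consumed as an input table;
  detecting them from video is out of scope, as is pose estimation
  itself.
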