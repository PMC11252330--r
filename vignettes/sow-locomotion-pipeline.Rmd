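---
title: "Methods: simulating and evaluating sow locomotion pose tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and evaluating sow locomotion pose tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sowpose)
```

## The problem

Lameness in sows is routinely graded by eye on a 0--3 ordinal locomotion
scale (0 = moves easily, 1 = visible lameness in at least one leg, 2 =
lameness with compensatory behaviours such as head dipping or back
arching, 3 = real reluctance to walk).  Markerless pose estimation
promises an objective alternative: track anatomical keypoints in lateral
and dorsal video of a walking sow and derive kinematics from them.
`sowpose` implements the analysis chain around such a study: the skeleton
definitions, the expert-vote consensus used to label videos, the metric
suite used to evaluate keypoint predictions, and the dataset bookkeeping
— together with a synthetic gait generator, because the labelled video
repository underlying the original models is not publicly available.

## Skeletons

Five skeletons are built in, related by keypoint removal:

* `lateral_13`: snout, neck, right/left hock, right/left pastern, dorsal
  neck, dorsal rump, rump, and the four hooves;
* `lateral_11`: `lateral_13` minus the dorsal neck and dorsal rump;
* `lateral_6`: snout, the four hooves, and the rump — the keypoints that
  survive a per-keypoint error screening;
* `dorsal_10`: head, neck, right/left scapula, thoracic, middle, lumbar,
  right/left pelvic, tail;
* `dorsal_7`: `dorsal_10` minus head, thoracic and lumbar.

Two vocabulary choices are deliberate.  The forelimb landmark is named
`pastern_right/left` with `metacarpal_*` accepted as an input alias (both
names occur in the field for the same landmark), and `dorsal_rump` takes
`dorsal_tail` as an alias while the dorsal-view `tail` keypoint remains
distinct.  Edge (bone) structure is cosmetic only: no metric in the suite
uses it, so skeletons are ordered keypoint sets.  Sub-skeleton membership
is defined by removal from the parent with order preserved, which the test
suite checks against all built-in parent/child pairs.

## The gait generator: a stated world

The generator is kinematic, not biomechanical.  The locomotion scoring
system describes behaviour, not motion equations, so the generator's
contract is only to produce controllable, score-monotone signatures:

* body keypoints translate at `speed` px/frame (default frame: 1920x1080
  at 15 fps, the recording configuration of the source study);
* limb keypoints follow a four-phase walk (cycle phase offsets 0, 0.5,
  0.25, 0.75 for RF/LF/RH/LH) with horizontal swing amplitude
  `stride_amp` and half-sine vertical lift `lift_amp`;
* lameness reduces swing and lift by `(1 - asymmetry)` on **both limbs of
  the affected side**.  A single-limb reduction was considered and
  rejected: the stride-asymmetry index averages left/right excursions
  over both hoof pairs, and the side-wide reduction is what yields the
  clean closed form `SA = asymmetry / (2 - asymmetry)` that anchors the
  generator's tests (it also reads naturally as compensatory shortening
  of the lame side);
* the snout oscillates vertically with amplitude `head_amp`, phase-locked
  to the affected-side forelimb (head dipping); mid-spine keypoints are
  offset upward by `arch_amp` (back arching); dorsal-view keypoints sway
  laterally with amplitude `sway_amp`, the off-side half-cycle damped by
  `asymmetry`;
* Gaussian labelling noise (`noise_sd`) and per-keypoint occlusion are
  applied last.  Occlusion defaults are side-asymmetric in the lateral
  view (0.15 for the left/far-side hoof family vs 0.02 elsewhere),
  because the camera films the animal's right side and the far hooves are
  regularly hidden by the body.

Per-score presets (`inst/extdata/gait_presets.csv`) are **invented**,
chosen once to be strictly score-monotone in asymmetry (0, 0.15, 0.35,
0.55) and head amplitude (0, 8, 16, 24 px) with slowing speed and, for
score 3, a slightly shortened stride.  They were not tuned against any
test outcome; the monotonicity acceptance check exercises the presets as
stated.  What a green generator test establishes is therefore internal
consistency (the generator produces the signatures it claims, and the
index recovers them), *not* fidelity to real sow kinematics: real gait
has variable cadence, non-sinusoidal stance/swing asymmetry, camera
perspective effects and correlated labelling error, none of which are
modelled.

The stride-asymmetry index measures hoof excursions relative to the rump
keypoint (removing body translation exactly), segments cycles at upward
mean-crossings, and needs at least two complete cycles; with the default
cadence of 0.05 cycles/frame that means roughly 60 frames or more.

## Expert consensus and the DBA statistic

A panel (13 experts in the source study) scores each lateral video 0--3.
The final score requires a strict majority (> 50%); exact ties are
unresolved, because "more than 50%" is the stated rule.  Confidence in
the answer is graded by the difference-between-answers statistic

\[ DBA = \max(v) - (\mathrm{sum}(v) - \max(v)) = 2\max(v) - \mathrm{sum}(v), \]

mapped through ordered half-open bands: below -1, 0% confidence; [-1, 0),
25%; [0, 1), 75%; [1, 2), 100%.  Two caveats are surfaced rather than
corrected.  First, the verbal description of the formula conflicts with
the displayed algebra; the displayed formula is authoritative here, and
both defensible readings of "loc scores" (the raw vote vector, default,
or the set of distinct answered scores) are implemented behind `mode`.
Second, the bands behave oddly under the raw reading — a unanimous panel
of three 2-votes has DBA = -2 and lands in the 0% band — and values of 2
or more are unmapped by the published table; the default policy labels
them `out_of_range` (excluded from the repository), with a `clamp`
option.  No attempt is made to make the bands "sensible": they are the
published rule.

Outlier experts are removed by a concrete version of the study's
box-plot screening: an expert's deviation is their mean absolute
difference from the per-video panel median, and deviations beyond
Q3 + 1.5 IQR (type-7 quantiles; multiplier configurable) are flagged.
The repository builder then keeps videos with a resolved majority and a
75% or 100% band, and reports per-(score x band) counts and exclusion
percentages; lateral scores are transferred verbatim to paired dorsal
videos, which were not scored directly.

## Evaluation metrics

For a ground-truth pose with visibility flags \(v_i\), prediction errors
\(d_i\) (px), instance scale \(s\) and per-keypoint falloff constants
\(k_i\):

\[ OKS = \frac{\sum_i \exp(-d_i^2 / 2 s^2 k_i^2)\,\delta(v_i > 0)}
             {\sum_i \delta(v_i > 0)} \]

Ground-truth-visible keypoints missing from the prediction contribute 0
to the numerator and 1 to the denominator.  Numerical and design choices:

* **AP direction.**  The printed AP formula counts instances with
  \(OKS < T\), under which better predictions would *lower* AP.  The
  standard \(OKS \ge T\) counting is implemented, and `mAP` is the mean
  of AP over the threshold grid 0.50:0.05:0.95 (the convention of the
  framework used by the source study); `mAR` uses recall against the
  total ground-truth instance count, so wholly unpredicted instances
  count against recall only.
* **Falloff constants.**  The source study does not publish its \(k_i\);
  the default is a uniform \(k = 0.1\), configurable per keypoint.
* **Scale.**  \(s\) defaults to the square root of the bounding-box area
  over visible ground-truth keypoints (the sow-sized analogue of the
  person scale); a degenerate zero-area box is an error unless a floor is
  configured.  A fixed-scale mode exists chiefly so closed-form tests are
  exact.  PCK uses the same normalizer, with strict inequality
  \(d_i/s_n < \alpha\) (boundary values count incorrect) and default
  \(\alpha = 0.05\), the accurate end of the literature's 0.05--0.3
  range.
* **Matching.**  Videos here contain one animal, so matching is
  one-instance-per-frame; frames with no visible ground truth are skipped
  and counted.

Per-keypoint pixel errors (mean, median, IQR, missing counts) support the
screening that reduced the 13/10-keypoint skeletons to 6/7: keypoints are
ranked by descending error IQR, ties by descending mean, stable in input
order.

The metric stack is held to three kinds of oracle in the acceptance
suite: closed forms under isotropic Gaussian error (mean OKS
\(= s^2k^2/(s^2k^2+\sigma^2)\), mean distance \(= \sigma\sqrt{\pi/2}\),
PCK \(= 1 - e^{-(\alpha s)^2/2\sigma^2}\)) at n = 10,000; brute-force
loop implementations to 1e-12 on small random instances; and invariance
properties (translation invariance, scale covariance, AP monotone in the
threshold).  The published model benchmarks themselves (e.g. lateral
OKS 0.94 / mAP 0.90) are *not* reproduction targets: they require the
withheld labels.

## Dataset operations

Frames enter training only if every skeleton keypoint is visible.  The
train/test split is at video granularity (preventing temporal leakage),
with the test count rounded half-up from the 15% default and a minimum of
one video; paired lateral/dorsal videos always land on the same side.
Rounding and the pairing guard are choices made here for determinism —
the source study states only the 85/15 proportions.  Optional
stratification by score is off by default, since the study does not state
it.  Annotation I/O uses a long-format CSV (video_id, view, frame,
keypoint, x, y, visible) with coordinates serialized at 17 significant
digits so round trips are bit-exact; the wide-format trajectory export
mirrors the study's coordinates-only supplementary videos.

## Known limitations

The generator's realism limits are listed above.  Beyond those: the
consensus module implements exactly the published rules, including their
rough edges, so it should not be used as a general inter-rater agreement
tool (no kappa/ICC); multi-instance matching is greedy and untested
against crowded scenes; and the published per-model metric table is out
of reach by design, so agreement with it cannot be claimed — only
agreement with the independently computable oracles above.
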