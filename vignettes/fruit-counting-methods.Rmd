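---
title: "Counting fruit by tracking: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting fruit by tracking: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fruitmot)
```

## The problem

A camera on a vehicle drives at constant speed along a crop row. A detector
proposes one bounding box per visible fruit per frame; the tracker must link
those boxes into identities so that the crop can be counted as the number of
unique identities. Every identity switch (IDSW) — a fruit re-entering under
a new id after occlusion, overlap or a camera bump — inflates the count by
one. This package is the tracking, post-processing and evaluation side of
that pipeline; detection is out of scope and arrives as MOT-format text
plus an optional embedding sidecar.

## Motion model

Each track carries an 8-dimensional state `(cx, cy, a, h, vcx, vcy, va, vh)`
— box center, aspect ratio, height, and their per-frame velocities —
estimated by a linear Kalman filter with a constant-velocity transition
(unit time step of one frame) and no control input: the vehicle's ego-motion
is absorbed into the velocity states rather than modelled separately, which
is adequate when the vehicle speed is constant.

Noise is height-proportional so gating is scale-free: position standard
deviations are `w_pos · h` (default `1/20`) and velocity standard deviations
`w_vel · h` (default `1/160`); the dimensionless aspect component uses small
constants (`1e-2` state, `1e-5` velocity, `1e-2` measurement). Track birth
doubles the position weights and takes ten times the velocity weight, so a
fresh track is loosely gated until its velocity settles. These are the
long-standing DeepSort conventions; nothing in the fruit-survey setting
argues for different values, and all of them are configurable
(`kalman_model()`, `default_config()`).

Numerically, the gain and the Mahalanobis form are solved through a Cholesky
factorization of the innovation covariance rather than an explicit inverse,
and covariances are re-symmetrized after every step; the test suite checks
symmetry and positive semidefiniteness over 1000 random cycles and agreement
with a plain textbook implementation to `1e-8`.

## Association

Candidate matches are scored by appearance and gated by motion:

* **Cascade matching** (confirmed tracks, by increasing
  `time_since_update`): cost is the *minimum* cosine distance between the
  detection embedding and the track's gallery (budget 100 embeddings), so
  one good historical view suffices. Pairs whose squared Mahalanobis
  distance exceeds the χ²₄ 0.95 quantile (9.4877) are infeasible; accepted
  pairs need cosine distance ≤ 0.2. The appearance/motion weighting is
  deliberately all-or-nothing — appearance is the cost, motion only a gate —
  because fruit of one cultivar look alike *between* identities too, and a
  blended cost would let motion noise override a clear appearance match; the
  weighting is exposed through the two thresholds rather than a mixing
  coefficient.
* **IOU fallback**: tentative tracks and confirmed tracks missed exactly one
  frame compete for the remaining detections at `1 − IOU ≤ 0.7`.
* **Assignment** is the Hungarian method (shortest augmenting path with dual
  potentials), with infeasibility encoded as a large finite sentinel cost
  (`1e5`) excluded afterwards, and ties broken toward the lowest
  (track, detection) index pair by an infinitesimal perturbation for
  reproducibility. The solver is cross-checked against exhaustive
  permutation minimization up to 6×6.

## Appearance re-matching

When a fruit's motion mutates — occlusion exit at a shifted position, camera
bump — the Mahalanobis gate rejects the true continuation even though the
fruit looks unchanged, and a new identity is born. After the two stages
above, still-unmatched detections are therefore compared to *lost* confirmed
tracks (missed between 1 and `max_age` frames) by pure cosine distance with
no motion gate. Three choices here were genuinely open:

* **Threshold** `θ_re = 0.15`, stricter than the cascade's 0.2: without a
  motion gate, appearance is the only evidence, so the bar is higher.
* **Placement after the IOU stage**, so re-matching only ever sees
  detections that normal matching could not claim and cannot interfere with
  it.
* **Motion-state reset**: a re-matched track's Kalman state is re-initialized
  from the detection (velocities zero) because the pre-mutation velocity is
  exactly what stopped matching; the gallery and history are kept. The
  bridged gap is *not* back-filled online — output stays causal; offline
  merging may interpolate later.

## Offline segment merging

Counting is offline, so after the run the finalized segments are cleaned up:

1. **Stability.** For each segment, the variance of per-frame cosine
   similarity to the segment's own normalized mean feature is computed.
   Segments shorter than `L_min = 5` frames or with variance above
   `v_max = 0.05` are *unstable* and removed from the count (kept in an
   audit log); variance in `(0.01, 0.05]` is *partially stable* — counted
   but never merged, since its appearance evidence is ambiguous; the rest
   are *stable*.
2. **Vote.** An ordered pair of stable segments (gap between 0 and
   `G_max = 45` frames, no temporal overlap) is eligible when the number of
   entries of the `M × N` pairwise frame-similarity matrix at or above
   `s_min = 0.8` strictly exceeds `M·N/2`.
3. **Position and shape.** The earlier segment's last center is extrapolated
   across the gap with its mean per-frame velocity (the uniform-linear-motion
   assumption); the pair passes if it lands within `p_max = 1.0`
   mean-box-diagonal units of the later segment's first center and the
   width/height ratios are within `r_max = 1.5`.
4. **Greedy fixpoint.** Eligible pairs merge in ascending-gap order (ties:
   higher mean similarity, then lower id); the merged segment — gap boxes
   linearly interpolated in tlwh space and flagged, features concatenated —
   re-enters the pool until nothing merges. Merging is idempotent and can
   only reduce the number of identities.

Continuous handovers (gap ≈ 0) and occlusion fragments (gap ≫ 0) are the
same rule in two regimes. The three-way stability split and all numeric
values above are this package's choices — the underlying idea fixes none of
them quantitatively — and every one lives in `default_config()`.

## Evaluation metrics

`clear_mot_evaluate()` follows the canonical CLEAR accumulation: per frame,
previous pairings persist while overlap stays ≥ 0.5, remaining pairs are
assigned by maximal overlap, and an identity switch is counted when a
ground-truth object's newly assigned id differs from its last known id.
`MOTA = (1 − (FP + FN + IDSW)/GT)·100`. For MOTP the summed per-match
"distance" is interpreted as *overlap*: MOTP is the mean IOU of matched
pairs in percent, which is the reading consistent with tracking precision
values in the high-80s; a `motp_mode = "distance"` switch reports mean
normalized center distance instead for anyone preferring the literal
reading. Counting uses `ACP`, `MAE`, `RMSE` exactly as defined, at full
precision internally, rounding half-up to two decimals only for display.

## The synthetic simulator

`generate_scenario()` emulates the capture regime the tracker assumes:
1920×1080 frames at 30 fps, fruit drifting horizontally at `camera_speed`
px/frame (plus per-fruit drift of 0.1 px/frame std), box heights 50–110 px,
detector dropout `p_miss`, uniform false positives, Gaussian box jitter, and
per-identity unit embeddings in 32 dimensions perturbed by Gaussian angular
noise. Occlusion events drop detections for an interval, optionally multiply
embedding noise through the reappearance frames, and apply a persistent
position jump at the interval's end — the concrete mechanism for a "motion
feature mutation". Everything is a deterministic function of the seed, and
the generator restores the caller's RNG state.

The three named presets map fruit density to 57 / 95 / 96 fruits over 360 /
510 / 600 frames and lower light to higher dropout and embedding noise
(3%→8% dropout, 0.06→0.12 noise) — chosen once as plausible survey regimes.
The `occlusion_suite` preset is 20 scripted scenarios (140 frames, 12
fruits) whose four events per scenario are engineered so each recovery mode
occurs by construction: two events jump ~2.3 box diagonals with clean
reappearance (only appearance re-matching can recover them — the jump
defeats the merge position check), one jumps ~0.6 diagonals with
noise-corrupted reappearance frames (only segment merging recovers it — the
corrupt frames defeat `θ_re` but not the segment-level vote), and one jumps
~0.8 diagonals cleanly (either improvement recovers it).

What the simulator does *not* model: real ReID embeddings (it uses abstract
unit vectors with identity-clustered structure, not CNN features of actual
fruit), photometric effects, correlated detector failures, non-linear fruit
motion, and rolling-shutter or stabilization artifacts. Passing the suite
therefore shows the *algorithms* behave as designed under their stated
assumptions, not that any particular detector/embedder meets those
assumptions on real footage.

## Problem sizes and degenerate inputs

The shipped tests run the full 2×2 improvement grid over the 20-scenario
suite (80 tracker runs at 140 frames × ~12 fruits), 10 scenes of CLEAR-MOT
cross-checking against a brute-force reference, 200 random assignment
matrices against exhaustive enumeration, and one full 57-fruit 360-frame
survey through the command-line interface example — sizes chosen so the
whole suite stays in the minutes range on one CPU while still exercising
every code path at realistic densities.

Degenerate inputs are handled at the boundary: boxes with non-positive width
or height are dropped at ingest with a warning (detectors do emit junk), not
errored mid-pipeline; detections below confidence 0.3 are ignored;
embeddings are renormalized on entry; out-of-order frames and
sidecar/detection row-count mismatches are hard errors; empty frames age
tracks; an empty ground truth makes MOTA an error rather than a silent 0/0.

## Known limitations

* Appearance re-matching assumes identities are separable in embedding
  space; with a weak embedder (or the hash fallback used when no sidecar
  exists) it should be disabled (`enable_rematch: false`), as should the
  merge vote.
* The merger's linear-extrapolation check assumes near-constant velocity
  over the gap; long gaps with curved motion will fail the position check
  and stay split (a conservative failure: over-counting, never
  cross-merging).
* CLEAR matching uses greedy persistence plus per-frame optimal assignment,
  the standard accumulator — not a global (min-cost-flow) association.
* Counting assumes each fruit appears once in the survey; loop closures
  (re-visiting the same row) are out of scope.
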