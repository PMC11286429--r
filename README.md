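# fruitmot

Counting fruit in orchard video surveys by multi-object tracking.

Yield estimation from video is usually done by *tracking-by-detection*: an
object detector proposes a box for every visible fruit in every frame, a
tracker links those boxes across frames into identities, and the crop is
counted as the number of unique identities. The hard part is keeping one
identity per fruit: occlusion by leaves, fruit overlap and camera bumps
change a fruit's apparent motion abruptly, the motion-gated matcher loses it,
and the fruit re-enters under a new identity — so it is counted twice.

`fruitmot` implements an improved DeepSort-style tracker for this setting,
aimed at surveys shot from a vehicle moving at constant speed along a crop
row (fruit in near-uniform linear image motion), plus the full evaluation
stack and a synthetic scene simulator so everything can be exercised without
video data. The package is detector-agnostic: it consumes MOT-format
detection files with an optional re-identification embedding sidecar.

## Method

Per-track motion is estimated by a constant-velocity Kalman filter on the
state `(cx, cy, a, h, vcx, vcy, va, vh)` (box center, aspect, height and
their per-frame velocities):

    predict:  x̂ₜ = F xₜ₋₁,        Pₜ = F Pₜ₋₁ Fᵀ + Q
    update:   y = z − H x̂ₜ,       K = Pₜ Hᵀ (H Pₜ Hᵀ + R)⁻¹
              xₜ = x̂ₜ + K y,      Pₜ = (I − K H) Pₜ

Each frame, detections are associated to tracks by the Hungarian algorithm
over three cascaded stages, plus the re-matching stage that is the point of
the package:

1. **Cascade matching** — cosine distance between the detection embedding and
   each track's embedding gallery, gated by the squared Mahalanobis distance
   `yᵀ (H P Hᵀ + R)⁻¹ y` at the χ²₄(0.95) quantile; recently updated tracks
   match first.
2. **IOU fallback** — `1 − IOU` cost for tentative and just-missed tracks.
3. **Appearance re-matching** — still-unmatched detections are compared to
   lost tracks by *pure* cosine distance with no motion gate, at a stricter
   threshold. This recovers identities whose motion mutated (the gate broke)
   but whose appearance did not; the track's motion state is re-initialized
   from the detection.
4. **Offline segment merging** — after the run, unstable segments (short, or
   with high variance of appearance self-similarity) are dropped; a pair of
   stable segments is merged when more than half of the `M × N` pairwise
   frame-feature cosine similarities exceed a threshold *and* linear
   extrapolation of the earlier segment lands on the later one with a
   compatible box shape. One mechanism handles both continuous identity
   handovers (gap ≈ 0) and occlusion fragments (gap up to 45 frames).

Evaluation: CLEAR-MOT metrics `MOTA = (1 − (FP + FN + IDSW)/GT)·100`, MOTP
(mean overlap of matched pairs), identity switches, and the counting metrics
over `N` videos

    ACP  = 100 · mean(1 − |GT − COUNT| / GT)
    MAE  = mean |GT − COUNT|
    RMSE = √(mean (GT − COUNT)²)

## Worked example

Simulate a low-density survey (57 fruits, 360 frames at 30 fps), track it,
and score it:

```r
library(fruitmot)

sc  <- generate_scenario(preset("low_density_medium_light", seed = 3))
res <- run_pipeline(sc$detections, sc$features)
res$count
#> [1] 57

clear_mot_evaluate(res$segments, sc$gt_segments)
#> <mot_report> GT 10338 | FP 7 FN 311 IDSW 2 | MOTA 96.9% MOTP 94.9%

counting_metrics(gt = sc$true_count, count = res$count)
#> <count_report> over 1 video(s)
#>  GT COUNT     ACP MAE
#>  57    57 100.00%   0
#> ACP 100.00% | MAE 0.00 | RMSE 0.00
```

All 57 fruits receive exactly one identity: the 2 residual identity switches
are repaired by segment merging before counting. The same pipeline runs from
the shell on MOT-format files:

```sh
inst/cli/fruitmot simulate --preset low_density_medium_light --seed 3 --out v1
inst/cli/fruitmot track --det v1/det.txt --emb v1/emb.txt --out pred.txt
inst/cli/fruitmot eval  --pred pred.txt --gt v1/gt.txt
inst/cli/fruitmot count --pred pred.txt --gt-counts 57
inst/cli/fruitmot ablate --seed 1   # 2x2 re-matching / merging grid
```

The `ablate` command runs the 20-scenario occlusion suite under the four
tracker configurations and prints identity switches and counting error per
configuration; with both improvements off the suite shows the most switches,
with both on the fewest.

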