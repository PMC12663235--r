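# maskrec

Reconciles two candidate binary segmentation masks of a stained tissue
image — typically a detector-driven mask that localizes cells well but
misses some and gets shapes wrong, and a dense segmenter mask with good
shapes but boundary overshoot — into a single mask that is better than
either input. It is aimed at cell/nuclei segmentation pipelines that end
up with two complementary predictions and need a principled fusion,
without any extra training.

## Method

Pixels where the masks agree are accepted (sets *F* and *B*); only the
disagreement set *A* is re-decided. The image is split into a K×K patch
grid (K = 5) and, per patch, two N-component RGB Gaussian mixtures
(N = 2) are fitted by EM on the unambiguous pixels — one for foreground,
one for background. Normalizing the class densities gives each pixel a
foreground probability

P(c) = p′(c | G<sup>f</sup>) / (p′(c | G<sup>f</sup>) + p′(c | G<sup>b</sup>)).

Each ambiguous pixel then gets a binary variable x, and the final
labeling maximizes

O<sub>idf</sub> − λ·O<sub>scf</sub>,&nbsp;&nbsp; with
O<sub>idf</sub> = Σ x·P + (1−x)·(1−P) and
O<sub>scf</sub> = Σ<sub>4-neighbor edges</sub> |x<sub>u</sub>−x<sub>v</sub>|·exp(−‖c<sub>u</sub>−c<sub>v</sub>‖₂/θ),

with λ = 2 and θ = 25 by default. The energy is submodular, so the
default backend solves it exactly by min-cut/max-flow; an equivalent
0-1 linear program (HiGHS) and a brute-force oracle are provided as
verification backends and agree on the optimum by construction (and by
test). Utilities cover the classic merging baselines (averaging at 0.5,
low-precision averaging at 0.9, tuned weighted sum), detector-guided
conversion of the fused mask to instances (ID transfer, k-means
splitting of merged cells, fresh IDs), small-object removal (< 20 px),
and the standard metrics: Dice, IoU, AJI, PQ (DQ·SQ) and Boundary-F1.

A seeded generator of histology-like scenes (elliptical nuclei,
patch-wise stain drift, noise, corrupted candidate masks) makes the
whole pipeline testable without any dataset.

## Worked example

```r
library(maskrec)

scene <- generate_scene(synthetic_spec(seed = 3))   # 128x128, 12 cells
scene_report(scene)
#>   n_cells fg_fraction dice_d dice_s n_ambiguous
#> 1      12       0.120  0.649  0.751        1444

m <- reconcile(scene$image, scene$mask_d, scene$mask_s)  # defaults: λ=2, θ=25, K=5, N=2
m <- remove_small_objects(m, 20)
dice_coefficient(m, scene$gt_semantic)
#> [1] 0.844

inst <- convert_to_instances(m, scene$itd_instances, scene$boxes)
metric_report(inst, scene$gt_instances)
#>    dice   iou   aji    pq    dq    sq   bf1 n_pred_instances n_gt_instances
#> 1 0.844 0.731 0.617 0.638 0.870 0.734 0.803               11             12
```

The detector mask (Dice 0.649, cells missing) and segmenter mask (Dice
0.751, boundaries overshot) disagree on 1444 pixels; re-deciding only
those pixels lifts Dice to 0.844. Across the packaged 25-seed benchmark
(`run_benchmark(seeds = 1:25)`), the reconciled mask beats the better
input on every seed, with a mean Dice gain of about 0.12 over the best
input.

The same pipeline is scriptable from a shell via `exec/maskrec`
(subcommands `synth`, `reconcile`, `merge`, `instances`, `metrics`,
`run`, `bench`).

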