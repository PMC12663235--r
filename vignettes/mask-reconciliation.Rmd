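---
title: "Reconciling candidate cell segmentation masks by integer programming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconciling candidate cell segmentation masks by integer programming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maskrec)
```

## The problem

Weakly supervised cell and nuclei segmentation pipelines often produce
*two* candidate masks for the same stained tissue image: one driven by a
cell detector (good at localizing cells, weaker on shapes, and prone to
missing cells entirely) and one from a dense segmenter (good shapes, but
with boundary overshoot and merged cells). The two masks agree on most
pixels; the information that distinguishes a good fusion from a bad one
is concentrated in the pixels where they *disagree*.

`maskrec` fuses such a pair by accepting every pixel the masks agree on
and re-deciding only the disagreement pixels, using two sources of
evidence: patch-local color statistics and local spatial coherence.

## The model

Let $M_D$ and $M_S$ be the two aligned binary masks. Pixels split into

* $F$ — both masks say foreground (accepted as foreground),
* $B$ — both say background (accepted as background),
* $A$ — the masks disagree (re-decided).

**Patch-local intensity model.** Staining intensity varies across a
slide, so a single image-wide color model of "cell" vs "background" is
noisy, while a *patch-local* one is informative. The image is split into
a $K \times K$ grid of patches (default $K = 5$). In each patch two
$N$-component full-covariance Gaussian mixtures over RGB are fitted by
EM — one on the patch's $F$ pixels, one on its $B$ pixels (default
$N = 2$); ambiguous pixels are excluded from fitting. The mixture
density of a color $c$ is

$$p'(c \mid G) = \sum_{n=1}^{N} w_n \,
  (2\pi)^{-3/2} |\Sigma_n|^{-1/2}
  \exp\!\left(-\tfrac12 (c-\mu_n)^\top \Sigma_n^{-1} (c-\mu_n)\right),$$

and the two class densities are normalized against each other to give
the per-pixel foreground probability

$$P(c) = \frac{p'(c \mid G^f)}{p'(c \mid G^f) + p'(c \mid G^b)},$$

with $1 - P(c)$ the background probability. Merging the per-patch maps
yields $P$ over the whole image.

**The labeling objective.** Each ambiguous pixel $(i,j)$ gets a binary
variable $x_{ij}$ (1 = foreground). The objective rewards labels that
agree with $P$,

$$O_{\mathrm{idf}} = \sum_{(i,j) \in A}
  x_{ij} P(c_{ij}) + (1 - x_{ij})\,(1 - P(c_{ij})),$$

and penalizes label changes across 4-neighbor edges between
similar-colored pixels,

$$O_{\mathrm{scf}} = \sum_{\text{edges } (u,v)} e_{uv} S_{uv},
\qquad S_{uv} = \exp\!\left(-\frac{\lVert c_u - c_v \rVert_2}{\theta}\right),$$

where $e_{uv} = |x_u - x_v|$ indicates a label change. The final mask
maximizes $O_{\mathrm{idf}} - \lambda\, O_{\mathrm{scf}}$ subject to the
edge constraints, with $x$ fixed to 1 on $F$ and 0 on $B$. Edges wholly
inside $F \cup B$ are constants and are dropped; edges between an
ambiguous pixel and a fixed pixel are folded into that pixel's unary
term (`build_problem()` does this bookkeeping, and reported objective
values always include the folded terms, so they are comparable across
solvers).

## Solvers

Three interchangeable backends solve the same problem:

* **`solve_maxflow()`** (default). For $\lambda \ge 0$ all discontinuity
  penalties $\lambda S$ are non-negative, so the binary energy is
  submodular and an exact global optimum is found by a minimum s-t cut
  (unary gains become terminal capacities, $\lambda S$ pairwise
  capacities; `igraph`'s max-flow does the cut). Although sparse-graph
  solvers are sometimes described as approximate in this setting, for
  this binary objective min-cut is exact, and the package verifies
  equality with the 0-1 program on every test instance.
* **`solve_ilp()`**. The absolute values are linearized as
  $e \ge x_u - x_v$ and $e \ge x_v - x_u$; since the coefficient of $e$
  in the maximization is $-\lambda S \le 0$, $e$ is driven to
  $|x_u - x_v|$ whenever it matters. The 0-1 program is solved by the
  HiGHS branch-and-bound solver through a bundled Python helper
  (`solve_ilp_batch()` amortizes the interpreter start-up over many
  instances).
* **`solve_bruteforce()`**. Exhaustive enumeration for up to 20
  variables; the independent oracle the other two are tested against.
  Ties are broken toward the labeling that is smallest as a binary
  number in raster order, i.e. toward background.

All solvers pass a final optimality-preserving sweep that flips
variables to background when the flip leaves the objective exactly
unchanged, making tie behavior deterministic (in particular, with
$\lambda = 0$ a pixel with $P = 0.5$ resolves to background, so the
$\lambda = 0$ special case reduces exactly to thresholding $P$ at 0.5).

## Parameters

| parameter | default | meaning |
|---|---|---|
| `lambda` | 2 | weight of the smoothness penalty against the intensity term |
| `theta` | 25 | color-similarity scale, in 8-bit intensity units |
| `grid_k` | 5 | patch grid order; $K^2$ patches |
| `n_components` | 2 | mixture components per class per patch |
| `min_area` | 20 px | small-object removal threshold |

These defaults are the operating point the method was tuned to, and
`theta = 25` is meaningful only on the raw 0–255 scale, which is why
pixel intensities are never normalized. The merging baselines binarize
with the `>=` convention: plain averaging ("AP") at 0.5, making it
inclusive (OR) on disagreement pixels, and low-precision averaging
("LP") at 0.9, making it exclusive (AND); validation-weighted merging
renormalizes weight pairs that do not sum exactly to 1.

## Numerical choices and degenerate inputs

* **EM**: seeded k-means++-style initialization, at most 200 iterations,
  relative log-likelihood tolerance $10^{-4}$, one initialization per
  fit. A floor of $10^{-3}$ is added to covariance diagonals because
  histology patches can be nearly constant in color; without it EM
  produces singular covariances. Fewer distinct colors than components
  reduces the component count (down to 1). Fits are deterministic given
  the seed; the foreground and background fits of a patch share one
  derived seed so that swapping the roles of the two pixel sets maps
  $P \mapsto 1 - P$ exactly.
* **Degenerate patches**: a patch with no $F$ or no $B$ pixels (or a
  failed fit) falls back to a pair of image-level mixtures fitted on all
  $F$ and all $B$ pixels and is flagged in the map's provenance; if the
  whole image lacks one class, the patch gets $P = 0.5$.
* **Underflow**: if both class densities underflow to zero the pixel is
  uninformative and receives $P = 0.5$.
* **Patch grid**: base patch size $\lfloor H/K \rfloor \times \lfloor
  W/K \rfloor$ with remainder rows/columns absorbed by the last patch
  row/column; both image dimensions are treated symmetrically.
* **Connectivity**: the pairwise term uses 4-connectivity (down and
  right edges), exactly the pairs the objective enumerates; connected
  components elsewhere (small-object removal, instance conversion) use
  8-connectivity, the standard choice for blob-like nuclei.
* **Metric conventions**: Dice, IoU and Boundary-F1 are 1 when both
  masks are empty; PQ = DQ = SQ = 1 when both instance maps are empty;
  PQ matching uses strict IoU > 0.5 (the threshold above which matches
  are provably unique); Boundary-F1 uses a 2-pixel tolerance by default.
* **Instance conversion**: small-object removal is applied to the
  semantic mask *before* instance conversion. Components overlapping
  two or more detector instances are split by k-means on pixel
  coordinates with centers initialized at the detector box centers
  (spatial features only, since the initialization is spatial); a
  missing box falls back to the instance's pixel centroid and is
  logged. Fresh IDs for undetected regions start above the largest
  detector ID.

## The synthetic generator

`generate_scene()` emulates the regime the method targets, without any
external data: dark elliptical nuclei (default mean RGB (90, 40, 120))
on a pale background (default (220, 205, 225)), per-patch additive RGB
drift (sd 12, on the same $5 \times 5$ grid the intensity model uses, so
the fixtures stress the patch-local assumption), and i.i.d. Gaussian
pixel noise (sd 10), rounded and clipped to 0–255. Cells are placed by
rejection sampling without overlap; placement failure after 500 attempts
raises an error naming the cell. The detector mask drops each cell with
probability 0.2 and randomly dilates or erodes survivors by 2 px; the
segmenter mask dilates the ground truth by 2 px and flips boundary-band
pixels with probability 0.25. All randomness comes from five sub-streams
derived in fixed order from the scene seed, so scenes are bit-identical
across runs and independent of internal call order.

What the generator does *not* emulate: real H&E texture (chromatin
structure, overlapping nuclei, out-of-focus regions), stain
deconvolution physics, or correlated detector/segmenter errors. Passing
the packaged benchmark therefore shows that the reconciliation recovers
missed cells and trims overshoot when foreground and background are
separable in color patch-locally — the method's stated operating
assumption — not that it improves any particular real dataset.

## Problem sizes used by the tests

The shipped checks run at desk scale: oracle-equivalence tests compare
the three solvers on 200 random problems with at most 12 ambiguous
pixels and on 100 random $16 \times 16$ full-ambiguity instances; mixture
recovery uses 50 seeded draws of 2000 points; the end-to-end benchmark
reconciles 25 seeded $128 \times 128$ scenes with 12 cells each
(`run_benchmark()`), on which the reconciled Dice exceeds the best input
Dice on at least 80% of seeds.

```{r bench, eval = FALSE}
bench <- run_benchmark(seeds = 1:25)
mean(bench$improved)
plot_benchmark(bench)
```

## Known limitations

* Only binary (foreground/background) labeling; no multi-class energy.
* No diagonal smoothness edges and no long-range (fully connected CRF)
  refinement.
* The intensity model works in RGB only; stain-space (HED/LAB)
  transforms are out of scope.
* Brute force is capped at 20 variables; the ILP backend needs a Python
  with SciPy on the PATH (the min-cut backend is pure R and is the
  default).
* With `n_cells = 0` or empty masks all operations follow the declared
  empty-input conventions rather than erroring, which is the behavior a
  batch pipeline wants but may mask upstream mistakes.
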