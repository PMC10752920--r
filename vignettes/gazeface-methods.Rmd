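---
title: "Attention-guided multi-scale face modelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-guided multi-scale face modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gazeface)
```

This vignette documents the model implemented by `gazeface`, the
parameters that matter, the numerical choices made where the design was
genuinely open, and what the synthetic fixtures do and do not establish
about behavior on real data.

## The model

### Scale-space features

An image $f$ is embedded in a Gaussian scale space
$L(x, y; \sigma) = (f * g_\sigma)(x, y)$ with the scale schedule
$\sigma_k = \sqrt{2^{k-1}}$, $k = 1..10$, and the working grid halved
every two levels (`gridDownsample` $= 2^{\lfloor (k-1)/2 \rfloor}$), so
$\sigma$ doubles every two levels while the grid keeps pace. Blob
features are extrema of the scale-normalized Laplacian
$\nabla^2 L = t\,(L_{xx} + L_{yy})$ with $t = \sigma_k^2$; dark blobs
have a positive-definite Hessian of $L$, bright blobs a
negative-definite one, and responses with $\lambda_1 \lambda_2 \le 0$
(edges, saddles) are discarded for repeatability. Extrema that persist
across adjacent scales are linked — chains within a radius of $2\sigma$
of the coarser level, same polarity — and each chain is represented by
its strongest member.

Numerical choices, made once:

* $\sigma_k$ is the Gaussian **standard deviation** and $t = \sigma_k^2$
  its variance; this is the only reading consistent with grid halving
  every two levels.
* Scale normalization by $t$ is required for responses at different
  levels to be comparable at all; without it coarse responses vanish
  as $\sigma^{-2}$.
* Second derivatives use **fourth-order central differences**. The
  $O(h^2)$ error of the 3-point stencil is largest right after each grid
  halving (where the on-grid smoothing is smallest) and systematically
  depresses the levels following a downsample, biasing the across-scale
  argmax; the 5-point stencil removes that term. With it, a rendered
  Gaussian blob of width 4 px attains its maximal normalized response at
  level 5 ($\sigma_5 = 4$), the closed-form optimum.
* Smoothing is incremental (each level adds the variance increment on
  the current grid) and factor-2 area averaging happens **after**
  smoothing, so the subsampled signal is band-limited.
* Boundaries are handled by symmetric reflection everywhere; extrema in
  the 1-px border of a grid are discarded; an extremal plateau of equal
  values contributes its centroid.
* Extrema weaker than `minResponse = 0.02` (normalized response, images
  in $[0,1]$) are treated as noise. Without a contrast floor every
  ripple of pixel noise is a formal extremum and the fine-scale feature
  pool is dominated by points that carry no face structure.

### Feature density maps and model points

Per scale, the features of all training faces are pooled in the
normalized face frame $[0,1]^2$ (positions divided by image width and
height — training faces are aligned but may differ in size) and their
density is estimated with a Gaussian KDE evaluated on a fixed
128×128 grid. Bandwidth is Scott's rule per axis, with a floor of 0.005;
the estimate uses linear binning + FFT (`KernSmooth::bkde2D`), so it is
deterministic and fast enough to be recomputed hundreds of times during
convergence tracking. Model points are the strict local maxima of the
grid whose value is at least 70 % of the global maximum (closed
threshold; the global maximum is always included).

Convergence of the maps is monitored by updating the pooled KDE one
image at a time from a 25-image start and recording the Bray–Curtis
index and $1 - \mathrm{JSD}$ (base-2 logarithm, so bounded by 1) between
successive maps, both computed on the discretized grids renormalized to
sum 1. During a convergence run the bandwidth is frozen at its
initial-pool value so successive maps differ only through the data; a
stream of identical images then scores exactly 1 from the first update.

### Fixation-guided scale selection

Fixations are grouped by their ordinal index into $F_1 .. F_{12}$ and
pooled over observers and images in the same normalized frame as the
features (the two data sources come from different acquisitions, so a
shared frame is the only defensible common coordinate system). Each
per-scale feature cloud and each $F_i$ is clustered with k-means
(10 restarts); the number of clusters in $[1, 7]$ is chosen by the
Davies–Bouldin index. Because the index is undefined at $k = 1$, the
single-centroid solution is returned only when the best $k \ge 2$
clustering is itself poor (Davies–Bouldin above 1.5) — a documented,
configurable convention. The directed distance $d_{k,i}$ averages, over
feature cluster centers, the distance to the nearest fixation cluster
center; averaging over $i$ gives $d_k$, and the whole procedure is
repeated (default 100 times) with fresh initializations, reporting the
repetition mean and spread. Model scales are the local minima of $d_k$
(endpoints qualify against their single neighbor), intersected with the
levels usable by the descriptor.

### Patch descriptors and classifiers

At each model point a 25×25 patch is taken on the pyramid level's own
grid. The descriptor partitions the patch into 3×3 cells and computes
per cell a 16-bin histogram of unsigned gradient orientation weighted by
magnitude: 9 histograms, 144 components, L2-normalized with
$\varepsilon = 10^{-6}$. The "9 histograms × 16 bins" factorization is
the only one in which the histogram count is 9; the alternative (4×4
cells × 9 bins) is not used. One linear SVM (cost $C = 1$) is trained
per scale — standard for HOG sliding-window detectors and cheap enough
to evaluate at every pixel — on positives from the model points of every
training face and an equal total number of negative patches at seeded
uniform positions of the clutter images' same pyramid level. The
classifier is stored as an explicit weight vector and bias; output is
hard 0/1.

### The detection cascade

Face-size hypotheses follow a $\sqrt 2$-spaced factor schedule from "the
whole image spans 32 px" up to "a face spans 32 px at native
resolution", dropping factors whose working image would fall below the
25-px patch. At the coarsest model scale every pixel (stride 1) of the
working image is a candidate: patches at the scale's model-point offsets
inside the 32-px face frame are classified, and the candidate passes on
a **strict majority** of positive patches — the coarse stage is the
cascade's per-pixel gatekeeper, and a bare tie among its patches is not
evidence of a face; the strict rule also keeps its firing rate on
clutter below a few percent of pixels, which the confirmation stages
rely on. Survivors
are re-scored at each finer scale on a working image enlarged by
$2^{(k_c - k_f)/2}$ — the sigma-schedule ratio — with coordinates and
offsets scaled accordingly; a confirmation scale accepts when at least
half its patches (configurable) classify positive. A candidate accepted
at every scale becomes a square detection of side $32/f$.

Implementation notes:

* The coarse stage is evaluated densely: per-bin integral images give
  every pixel's 144-component descriptor in a handful of vectorized
  block operations, and the linear classifier reduces to one
  matrix-vector product. Finer stages see few candidates and evaluate
  patches individually.
* Working images are pre-smoothed with the residual on-grid sigma of the
  corresponding training level ($\sigma_k / g_k$), so detection patches
  see the blur the classifier was trained on.
* Working images are reflection-padded by the maximal model-point offset
  so faces at the image border keep all their patches evaluable —
  consistent with training, where patch extraction reflects at borders.
* Merging (`mergeDetections`) is off by default; when enabled it groups
  detections into connected components under the overlap relation
  (IoU ≥ 0.3, or intersection covering ≥ 0.6 of the smaller box, which
  links same-face re-detections across neighboring cascade scales) and
  replaces each group by its mean rectangle. The group mean, rather than
  the largest member, is used deliberately: with stride-1 evaluation a
  true face produces a tight cluster of near-duplicate windows, and a
  single oversized outlier absorbed into the group must not displace
  that consensus. `minNeighbors` optionally drops uncorroborated
  single-window groups, the standard practice for stride-1 cascades.

### Evaluation

IoU uses the half-open pixel convention. Matching is greedy in
descending IoU with a one-to-one constraint — a second detection on an
already-matched face counts as a false positive — and precision with
zero detections is reported as missing rather than 1. FDDB-style ellipse
annotations are converted to axis-aligned boxes by the closed-form
bounding rectangle of the rotated ellipse (angle 0 = major axis
vertical).

## The synthetic generator

The generator emulates three data sources: aligned frontal face crops
(250-px canvas, a skin-tone oval spanning ~72 % × 88 % of it), clutter
negatives (soft random ellipses, shading edges, pixel noise), and
per-observer fixation sequences. Faces carry dark Gaussian-profile
landmarks at two eyes, nose and mouth — the ground-truth landmark set —
plus rendered structure that gives the face its multi-scale profile:
pupils and nostrils (fine levels), eyebrows, eye sockets, a hair mass
and a chin shadow (coarse levels). Backgrounds around the oval are
seeded clutter of random mean level, as uncontrolled in-the-wild crops
have; this matters for the detector, whose coarse-scale patches overhang
the face frame. Landmark geometry jitters by sd 0.01 per image, blob
contrasts by 10 %, and pixel noise has sd 0.02.

Fixations are drawn from an index-dependent mixture over the face center
and the landmarks: the center weight decays linearly over the first four
indices, and fixation scatter shrinks from 0.08 to 0.02 across the
sequence — a coarse-to-fine schedule. Each of the 20 default observers
has a small idiosyncratic bias (sd 0.01) and a personal noise
multiplier.

What the fixtures do **not** emulate: pose, rotation and expression
variation, occlusion, illumination gradients, camera noise statistics,
and correlated saccade dynamics (fixation durations are not modelled).
Passing the fixture-based tests therefore shows the pipeline's internal
consistency — features land on the structures that generate them,
density maps converge, planted scale structure is recovered, rendered
faces are detected — not detection performance on photographs.

## Problem sizes

The shipped tests and the acceptance script use 300 training faces, 100
negatives, 20 observers and 40 single-face evaluation scenes (canvas
256 px; face sizes 64, 91 and 128 px — values on the cascade's factor
schedule). Scene evaluation merges the raw cascade output with
`mergeDetections(minNeighbors = 2)`: with stride-1 evaluation a real
face is always corroborated by neighboring windows, so uncorroborated
single-window groups are dropped before IoU scoring. Density-map convergence is tracked at level 2, where a face
contributes a few dozen features. The scale-selection recovery test uses
planted per-level clouds of 400 points, 10 profile repetitions and 20
seeded runs. These sizes were chosen so the full pipeline exercises
every module at stable statistics.

## Known limitations

* The detector is frontal-upright only; no rotation or pose invariance
  is attempted, and rectangles are square by construction.
* The binary classifier admits no confidence threshold, so
  precision/recall cannot be traded off after training.
* Sub-pixel/sub-scale interpolation of extrema is not performed; blob
  localization is quantized by the level grid.
* Scale selection compares cluster *centers* only; cluster shape and
  weight are ignored by design.
* With a single fixation-cluster structure close to several scales'
  feature clusters, the local-minimum rule can select adjacent scales;
  the Davies–Bouldin $k = 1$ convention (threshold 1.5) is a heuristic
  documented above.
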