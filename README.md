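# gazeface

Human-attention-guided multi-scale face modelling and detection in R.

Multi-scale part-based face detectors work well, but the choice of which
spatial scales to model is usually made by hand. `gazeface` implements an
alternative: let the scales be chosen by where people actually look.
The package

1. builds a **Gaussian scale-space pyramid** of each training face
   (10 levels, σ_k = √(2^(k−1)), grid halved every two levels), extracts
   blob features as extrema of the scale-normalized Laplacian
   ∇²L = t·(L_xx + L_yy), t = σ_k², discards edge responses by the Hessian
   definiteness test λ₁λ₂ > 0, and links extrema across scales;
2. pools the features of many aligned faces per scale into a **feature
   density map** (2-D Gaussian KDE on the unit face frame) and selects
   **model points** — local maxima within 70 % of the global maximum;
3. compares, per scale, k-means clusters of the feature clouds with
   k-means clusters of human **eye-tracking fixations** F₁…F₁₂ (Davies–
   Bouldin choice of k in [1, 7], 10 restarts, 100 repetitions) and
   selects the scales at local minima of the averaged cluster distance
   d_k — the scales whose features look most like human fixations;
4. trains one linear SVM per selected scale on 144-component HOG
   descriptors (25×25 patches at the model points; 9 histograms × 16
   orientation bins) and runs a **coarse-to-fine cascade**: the image is
   resized so a hypothesized face spans 32 px at the coarsest scale, every
   pixel is evaluated, and survivors are confirmed at the finer scales;
5. scores detections against ground truth with **IoU matching**
   (threshold 0.5, greedy one-to-one) and precision/recall curves.

A seeded synthetic generator supplies every input the pipeline needs:
aligned face images with landmark ground truth, clutter negatives,
annotated multi-face scenes (FDDB-style ellipse files), and per-observer
fixation sequences with a coarse-to-fine index structure.

## Worked example

```r
library(gazeface)

## training data: 300 aligned synthetic faces + 100 clutter negatives
faces <- lapply(1:300, function(s) generateFaceImage(faceSpec(seed = s))$image)
negs  <- lapply(1:100, function(s) generateNegativeImage(seed = 1000 + s))

## fixation-guided two-scale model (coarse sigma_7 = 8, fine sigma_4 = 2*sqrt(2))
model <- buildFaceModel(faces, negs, levels = c(7, 4), seed = 42)
model
#> FaceModel: scales [7, 4] (coarse to fine), reference face 32 px, patch 25 px
#>   level 7: 6 model point(s)
#>   level 4: 4 model point(s)

## detect faces in a synthetic scene and score against ground truth
scene <- generateScene(faceSizes = 128, canvas = 256, seed = 5005)
det <- mergeDetections(detectFaces(scene$image, model),
                       minNeighbors = 2, enabled = TRUE)
det[, c("x", "y", "w", "h", "score", "members")]
#>          x        y        w        h score members
#> 1 24.49305 29.90711 103.7937 103.6063     1      17
m <- matchDetections(det, scene$boxes, threshold = 0.5)
c(m[c("tp", "fp", "fn")], iou = round(m$matches$iou, 3))
#> $tp [1] 1   $fp [1] 0   $fn [1] 0   $iou [1] 0.824
```

Raw cascade output is one square per accepted candidate (side = 32 px /
resize factor); `mergeDetections` replaces each group of overlapping
windows by its consensus rectangle (here 17 corroborating windows), and
`matchDetections` reports a true positive because the IoU with the
annotated face box exceeds 0.5.

The scale-selection step itself:

```r
featsByScale <- lapply(setNames(1:7, 1:7), function(k)
  accumulateFeatures(lapply(faces[1:60], extractFeatures), k))
fix  <- generateFixations(do.call(rbind, faceSpec()$landmarks),
                          observerModels(20), nImages = 120, seed = 1)
prof <- scaleAffinityProfile(featsByScale, partitionFixations(fix),
                             nRep = 100, seed = 1)
selectScales(prof, usableLevels = 1:7)
```

returns the levels at local minima of d_k, coarse first.

A thin command-line front end with subcommands `synth`, `build-density`,
`select-scales`, `train`, `detect` and `evaluate` is installed at
`inst/cli/gazeface.R`.

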