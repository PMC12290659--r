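# PLItexture

Self-supervised texture representations for 3D polarized light imaging
(3D-PLI) of nerve fiber architecture, in R.

3D-PLI images unstained brain sections between rotating polarizers.
Every pixel yields a sinusoidal intensity profile

$$I_\rho = \tfrac{I_T}{2}\,\bigl(1 + \sin(2\rho - 2\varphi)\sin\delta\bigr),
\qquad \delta \approx \frac{2\pi t\,\Delta n}{\lambda}\cos^2\alpha,$$

from which transmittance $I_T$, in-plane fiber direction $\varphi$
(mod $\pi$) and retardation $r=|\sin\delta|$ are retrieved by harmonic
analysis. Serial sections registered into a common 3D reference space
describe fiber architecture at micrometer resolution — but annotated
reference data are scarce. This package implements a self-supervised
route to texture features for such data, aimed at researchers working
with polarimetric or other multi-channel histology:

* **physics** — forward signal model, Fourier parameter retrieval,
  simplified inclination estimation, the 3-channel encoding
  $(I_T,\ r\cos 2\varphi,\ r\sin 2\varphi)$;
* **synthetic phantoms** — multi-section stacks with radial/tangential
  cortical fibers, parallel and crossing white-matter bundles,
  per-section affine jitter, noise, and analytic ground truth
  (masks, region labels, cortical depth, curvature, obliqueness);
* **augmentations** that transform $(I_T, \varphi, r)$ jointly and
  consistently (attenuation/thickness scaling, affine warps and blur via
  a transmittance-weighted complex average, Jacobian direction
  correction);
* **3D-context contrastive learning** — anchor/positive pairs sampled on
  an in-plane circle (CL-2D) or across sections on a 3D sphere (CL-3D),
  a width-reduced 50-layer residual encoder (256-dim features at width
  1/8), projection head, and InfoNCE loss with cosine similarity — the
  full training stack (conv/batch-norm/pool kernels, Adam, backprop) is
  implemented in the package with RcppArmadillo;
* **classical texture baselines** — histogram statistics (15), local
  binary patterns (90), grey-level co-occurrence features (36) and their
  combination (141), computed on $(I_T, r, \hat\varphi)$ with
  $\hat\varphi$ the circular Sobel direction-gradient map;
* **downstream evaluation** — PCA component maps, two-step clustering
  (k-means + Ward agglomeration) with silhouette curves and
  cross-section IoU, linear probing with minimal labels, ridge
  regression of cortical morphology, and RBF-kernel retrieval.

## Worked example

Simulate a phantom, train a small CL-3D encoder, and probe the learned
features with 30 labels per class:

```r
library(PLItexture)

stack <- makePhantom(phantomSpec(), seed = 7)
stack
#> PLIStack: 8 sections of 256 x 256 px, spacing 60 um, pixel 1.3 um
#>   morphology: depth, curvature, obliqueness

cfg <- encoderConfig(batchPairs = 64L, learningRate = 3e-3,
                     standardizationBatches = 16L)
mod <- trainContrastive(stack, cfg, mode = "cl3d", radiusUm = 30,
                        patchPx = 48L,
                        policy = augmentationPolicy(cropPx = 32L),
                        steps = 600L, trainSections = 1:6, seed = 1)
round(c(first = mean(head(mod$log$loss, 5)),
        last = mean(tail(mod$log$loss, 5))), 3)
#> first  last
#> 4.864 4.482

train <- labeledPatchDataset(stack, 48L, 16L, "region", sections = 1:6)
test  <- labeledPatchDataset(stack, 48L, 16L, "region", sections = 7:8)
train <- train[train$class > 0, ]; test <- test[test$class > 0, ]
feat <- function(ds) encodePatches(mod, mapply(function(s, r, c)
  extractPatch(stack, s, r, c, 48L), ds$section, ds$row, ds$col,
  SIMPLIFY = FALSE))
linearProbe(feat(train), train$class, feat(test), test$class,
            nPerClass = 30L, repeats = 10L, seed = 1)
#>    n    meanF1        seF1
#> 1 30 0.9041857 0.004959733
```

The training loss falls from the random-pair baseline
($\ln 127 \approx 4.84$ for 64 pairs) as the encoder aligns spatially
neighboring views; the probe then separates the phantom's four fiber
configurations (radial, tangential, parallel bundle, crossing) at macro
F1 ≈ 0.90 from 30 labels per class on held-out sections. Feature maps
for whole sections come from `inferFeatureMap()` (learned) or
`classicFeatureMap()` (baselines) on a common tile grid, and feed
`twoStepCluster()`, `crossSectionIoU()`, `morphologyRegression()` and
`rbfRetrieval()`.

A thin command-line front end over the same functions is available at
`inst/cli/plitexture.R` (subcommands `simulate`, `sample-pairs`,
`train`, `infer`, `features`, `cluster`).

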