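# cellmiml

Label-free cell classification by fusing bright-field images with
biomechanical features from microfluidic constriction transits — for
deformability-cytometry practitioners and method developers who want a
fully tested, dependency-light R implementation they can audit end to end.

## The idea

A cell forced through a constriction narrower than its own diameter must
deform to pass. Its transit is summarized by a small feature vector
`m = (DI, TT, vmax[, DIR])`:

- **DI** (deformation index): `DI = (a − b) / (a + b)` for the fitted
  major/minor axes `a ≥ b`; 0 for a circle, → 1 as the cell elongates.
- **TT** (transition time): time for the centroid to traverse the
  constriction between entry and exit planes.
- **vmax**: peak centroid velocity inside the constriction, normalized by
  the imposed flow velocity.
- **DIR** (optional): mean |dDI/dt| over the squeeze-and-recover cycle.

The multimodal model fuses an image embedding with these features. A
residual convolutional encoder (7×7/2 stem + BN + ReLU + max-pool; four
stages of residual blocks, filters doubling from 64; global average pool)
has its final classifier replaced by an identity, giving `z1 = F_CNN(I)`.
A small feed-forward branch maps `m` to `z2 = f_NN(m)`. The concatenation
`u = [z1; z2]` passes through

```
h2 = ReLU(BatchNorm(Linear(u)))      # width 64
h3 = ReLU(BatchNorm(Linear(h2)))     # width 16
ŷ  = Softmax(Linear(h3))             # n_classes
```

Classification quality is assessed with accuracy, precision, recall,
F1 = 2TP/(2TP+FP+FN) and AUC under grouped, stratified 5-fold
cross-validation (a cell's two frames never straddle folds). Classical
baselines on `m` alone (LR, SVM, DT, RF, KNN, and a d→32→16→2 network) and
transfer learning (re-initialized head, optional freezing) complete the
workflow.

Everything runs on synthetic transits: a phenomenological simulator
(effective compressed gap `g_eff = gap + (D − gap)·s/(s + s0)`, area
conservation `a = D²/b`, stiffness-dependent friction) generates cells
whose ground truth is known exactly, with a renderer whose dials control
what images may reveal. Neural networks are trained by an in-package
engine (C++ im2col + BLAS, backprop verified against finite differences).

## Worked example

Two populations with identical morphology (visual overlap 1, class-free
rendered shapes) but different stiffness — only mechanics separate them:

```r
library(cellmiml)

pop <- population_config(
  n = c(300, 300),
  diameter_mean  = c(14.2, 14.2), diameter_sd = c(3, 3),
  stiffness_mean = c(2, 4),       stiffness_sd = c(0.6, 1.2),
  texture_overlap = 1, shape_source = "class_free")

ds  <- make_dataset(pop, channel_geometry(), image_spec(),
                    out_dir = file.path(tempdir(), "demo"), seed = 1)
man <- read_manifest(ds$manifest_path)
head(man[, 1:6], 3)
#>     cell_id class    di tt_ms vmax_norm dir_per_ms
#> 1 soft_0001  soft 0.485  36.9     0.815    0.01275
#> 2 soft_0002  soft 0.516  36.7     0.818    0.01367
#> 3 soft_0003  soft 0.399  39.6     0.758    0.00988

fm    <- feature_matrix(man, c("di", "tt", "vmax"))
folds <- make_folds(fm$cell_ids, man$class, k = 5, seed = 1)
compare_models(fm, folds, kinds = c("lr", "svm", "knn", "mlp"),
               feature_sets = list(c("di", "tt", "vmax")), seed = 1)
#>   model   features mean_acc sd_acc
#> 1    lr di+tt+vmax    0.862 0.0394
#> 2   svm di+tt+vmax    0.878 0.0394
#> 3   knn di+tt+vmax    0.877 0.0308
#> 4   mlp di+tt+vmax    0.875 0.0377
```

The soft class deforms more (DI ≈ 0.5) and transits faster; every tabular
classifier separates the classes at ~0.87 from three features alone. Now
the central comparison — an image-only CNN against the fused model on the
same grouped 4:1 split (compact desk-scale encoder, 6 epochs):

```r
sp <- split_dataset(man, seed = 1)
tr <- load_examples(man, sp$train, c("di", "tt", "vmax"))
va <- load_examples(man, sp$val,   c("di", "tt", "vmax"), bounds = tr$bounds)
te <- load_examples(man, sp$test,  c("di", "tt", "vmax"), bounds = tr$bounds)

ecfg <- encoder_config(base_filters = 8, blocks_per_stage = 1, input_size = 64)
ccfg <- ecfg; ccfg$head <- "classifier"
cnn  <- train_image_classifier(build_encoder(ccfg, seed = 1), tr, va,
                               epochs = 6, seed = 1)
fus  <- train_miml(build_fusion(ecfg, fusion_cfg = fusion_config(n_cnn = 64, d = 3),
                                seed = 1), tr, va, epochs = 6, seed = 1)

acc <- function(p, y) mean(max.col(p) - 1 == y)
acc(encoder_predict_prob(cnn$model, te$images), te$y)
#> image-only CNN test accuracy : 0.567
acc(miml_predict_prob(fus$model, te$images, te$m), te$y)
#> fused image+mechanics        : 0.792
```

The images were constructed to carry no class signal, so the CNN sits near
chance while the fused model recovers the mechanical separation — the
fusion benefit the package exists to demonstrate. (At the acceptance
suite's five-seed scale the mean gap is ≈ 30 accuracy points.)

A command-line interface covers the same pipeline
(`Rscript inst/cli/miml.R simulate|extract|split|train-tabular|train-cnn|
train-miml|evaluate|transfer|embed --flags`), and `vignettes/methods.Rmd`
documents the model, the simulator, every tunable default and the known
limitations.

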