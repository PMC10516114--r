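---
title: "Methods: multimodal image-mechanics classification of transiting cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal image-mechanics classification of transiting cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Deformability cytometry classifies cells label-free by how they respond to
mechanical stress: a cell driven through a microfluidic constriction
narrower than its own diameter must deform to pass, and the way it deforms
carries information that bright-field morphology alone does not. `cellmiml`
implements a complete, tested version of this workflow: a constriction
transit is summarized by a small vector of biomechanical features,

* **DI** — deformation index, `(a - b) / (a + b)` for the fitted major and
  minor axes: 0 for a circle, approaching 1 as the cell elongates;
* **TT** — transition time, the time the centroid takes to traverse the
  constriction between its entry and exit planes (ms);
* **vmax** — the cell's peak velocity inside the constriction, normalized
  by the imposed flow velocity (dimensionless, 1 in the free-advection
  limit);
* **DIR** (optional 4th feature) — the time-averaged absolute rate of
  change of DI over the squeeze-and-recover cycle (1/ms);

and a multimodal network fuses an image embedding with these features. The
image branch is a residual convolutional encoder (7x7 stride-2 stem with
batch normalization, ReLU and 3x3 stride-2 max pooling; four stages of
residual blocks with filters doubling from 64, stride-2 downsampling with
1x1 projection shortcuts at stages 2-4; global average pooling). Its
terminal classifier is replaced by an identity, so the image contributes
its embedding `z1`. The mechanical vector `m` passes through a small
feed-forward branch (d -> 32 -> 16) contributing `z2`. The concatenation
`u = [z1; z2]` feeds a fusion head of Linear-BatchNorm-ReLU (to 64),
Linear-BatchNorm-ReLU (to 16) and Linear-Softmax. The same 32/16
feed-forward architecture with a 2-way softmax output is the stand-alone
tabular network (690 trainable parameters for d = 3); classical baselines
(logistic regression, RBF-kernel SVM, CART decision tree, random forest,
k-nearest neighbours) complete the tabular comparison.

Everything is exercised on synthetic data: the package ships a transit
simulator and frame renderer whose ground truth is known exactly, so every
claim a test makes is checkable against construction.

## The transit simulator

A full fluid-structure solver is out of scope; the simulator is a
phenomenological model chosen to be the *minimal* mechanics that reproduces
the qualitative laws the classifier relies on — softer cells deform more,
transit faster, and reach higher peak velocity:

* effective compressed gap: `g_eff = gap + (D - gap) * s / (s + s0)`, with
  stiffness `s` (dimensionless stretching-resistance analogue), diameter
  `D` (um) and scale `s0 = 5`. Soft cells (`s -> 0`) squeeze fully to the
  physical gap; rigid cells (`s -> Inf`) barely deform.
* minor axis: exponential relaxation toward `g_eff` inside the
  constriction (and back toward `D` outside) at rate `relax_rate / s`
  (default 2/ms), integrated exactly per step, so the scheme is
  unconditionally stable.
* major axis: 2-D area conservation, `a = D^2 / b`.
* velocity: `v = u_flow / (1 + kappa * s * (D - gap) / gap)` inside the
  constriction (`kappa = 0.1`), `u_flow` outside.

Defaults are anchored to the device this framework targets: gap 5.2 um,
depth 20 um, diameters 14.2 +/- 4.4 um and 13.5 +/- 1.5 um for the two
default populations, flow velocity 1 um/ms, constriction length 30 um (not
reported for the reference device; configurable), time step 0.1 ms.

Numerical choices worth knowing:

* Cells no wider than the gap advect freely and keep DI = 0; this is a
  valid regime, not an error.
* The trace continues briefly *past* the exit plane until the minor axis
  has recovered, so the recovery limb of DI — which the DIR definition
  averages over — is observable. Entry/exit indices, and hence TT and
  vmax, are unaffected.
* Extremely stiff cells transit extremely slowly under the friction law.
  Rather than letting the step count grow unboundedly, the simulator
  estimates the transit duration and coarsens the time grid past a step
  cap (default 20 000), and position updates land exactly on the entry
  plane so a coarse grid cannot stride across the constriction.

## The frame renderer

Each cell yields two grayscale frames mirroring the two-image acquisition
protocol: one just before the entry plane (undeformed) and one at maximal
squeeze. A frame is an anti-aliased filled ellipse (4x4 subpixel coverage
sampling) with the trace's instantaneous axes, near the frame centre up to
a small uniform crop jitter (default 1/12 of the frame side, emulating
imperfect detector crops), plus intra-cell speckle texture and additive
Gaussian pixel noise, clipped to [0, 1]. Files are 8-bit grayscale PNG;
the manifest CSV columns are fixed and ordered
(`cell_id, class, di, tt_ms, vmax_norm, dir_per_ms, img_entry,
img_squeezed`).

Two dials control what the images can reveal:

* `texture_overlap` in [0, 1]: at 1 the two classes' texture distributions
  are identical; at 0 they are fully distinct. Two signal kinds are
  available: `"granularity"` (default) separates the intra-cell speckle
  scale at equal mean brightness — the class evidence stays spatially
  inside the cell, which class-activation diagnostics require — and
  `"brightness"` offsets the mean interior intensity, a coarser cue that
  remains learnable at low resolutions. (A brightness cue makes Grad-CAM
  highlight the *absence* of brightness for the darker class, i.e.
  background; that is a property of the cue, not of the method.)
* `shape_source`: `"trace"` renders the cell's own simulated shape;
  `"class_free"` renders a shape simulated from a stiffness resampled from
  the pooled class mixture, so image distributions are identical across
  classes while the manifest features still reflect the true mechanics.
  This is how "images identical across classes" worlds are built.

What the generator does *not* emulate: optics (point-spread function,
defocus, illumination gradients), multi-cell interactions and collisions,
membrane-wrinkle texture, day-to-day acquisition drift. A green test on
synthetic data therefore establishes that the pipeline recovers what the
generator put in — not that it would meet any particular accuracy on real
microscopy.

## Feature extraction

Segmentation is a global Otsu threshold (cells render brighter than
background; the threshold is the upper edge of the selected histogram bin),
3x3 morphological closing, and retention of the largest 8-connected
component — a deliberate replacement of a trained detector by a
dependency-free method adequate for single-cell frames. Ellipse axes come
from second-order moments: for a filled ellipse the principal second
moments are `(a/4)^2` and `(b/4)^2`. Two discretization conventions
matter and are both implemented: binary pixel-centre masks miss the
within-pixel spread (+1/12 correction), while an anti-aliased coverage
field is the indicator already box-smoothed by one pixel (-1/12). DI from
images uses intensity-estimated coverage weights, which restores subpixel
accuracy that a binary mask quantizes away; the round-trip error over the
tested size range stays below 0.02 DI units. Components thinner than 2 px
are rejected as unresolvable.

Feature normalization is min-max to [0, 1] with bounds fitted on the
training split only and reused (with clipping) on validation/test splits;
DI is pre-normalized by definition and keeps fixed bounds (0, 1). A
constant vector normalizes to zeros with a warning.

## Training engine and its calibrations

The networks are trained by an in-package backpropagation engine
(im2col/col2im and max-pooling in C++, GEMM via BLAS, hand-written layer
gradients verified against central finite differences to 1e-5, Adam
optimizer). Choices a user may care about:

* batch size 32, learning rate 1e-3, cross-entropy loss; weight init is
  He-scaled Gaussian, seeded, and every source of randomness derives from
  one run seed through named substreams.
* batch-norm running statistics use momentum 0.3. Desk-scale runs have few
  minibatches per epoch; with the conventional 0.1 the eval-mode statistics
  lag the trained weights by about an epoch, which visibly corrupts
  validation accuracy early in training.
* per-epoch training accuracy is accumulated over the epoch's minibatches
  (training-mode forward); validation accuracy is an eval-mode pass. The
  best-validation epoch's parameters and statistics are retained.
* fine-tuning re-initializes only the final classification layer, freezes
  batch-norm statistics (tiny batches cannot re-estimate them stably),
  uses batch size 8 and decoupled weight decay 0.05 on weight matrices —
  standard small-sample practice. Freeze policies: `none`, `encoder`,
  `all-but-head`.
* the feature MLP early-stops on a validation-loss plateau (patience 40
  epochs, 15% stratified validation split), less noisy than accuracy at
  desk-scale validation sizes.

Classical baselines use conventional hyperparameters, recorded on the
fitted object: ridge logistic regression (C = 1), RBF-kernel SVM trained
by the Pegasos subgradient method (C = 1, gamma = 1/(d * mean variance),
Platt scaling for probabilities), CART with Gini impurity and unlimited
depth, random forest of 100 bootstrap trees with mtry = floor(sqrt(d)),
KNN with k = 5 and lowest-index tie-breaking.

## Evaluation and diagnostics

Metrics derive from confusion counts — accuracy `(TP+TN)/total`, precision
`TP/(TP+FP)`, recall `TP/(TP+FN)`, F1 `2TP/(2TP+FP+FN)` — with zero
denominators reported as 0 plus a warning flag. ROC sweeps the unique
scores with ties grouped; AUC (trapezoid) equals the Mann-Whitney rank
statistic, and the tests hold it to that oracle at 1e-9. Cross-validation
plans are stratified at the cell level and grouped by cell id, so the two
frames of a cell can never straddle folds; splits follow the 4:1
train+val : test protocol with 5-fold CV inside the 80%. Both per-image
and per-cell (probability-averaged) metrics are reported, since headline
accuracies can be quoted either way. Grad-CAM maps "penultimate"/"last" to
the final residual blocks of the last two stages; 2-D latent embeddings
delegate to t-SNE with a row-count-adaptive perplexity.

## The benchmark worlds

The acceptance suite is property-based; its data worlds are fixed here:

* *Fusion benefit*: 300 cells per class, shared diameter distribution
  (14.2 +/- 3 um), stiffness 2 +/- 0.6 vs 4 +/- 1.2 (about two standard
  deviations of separation per feature), visual overlap 1 with class-free
  shapes, 64x64 frames. Only mechanics separate the classes; the fused
  model must beat the image-only CNN by at least 5 accuracy points over
  five seeds (observed: about 30 points, with the image-only CNN at
  chance).
* *No harm*: stiffness identically distributed across classes, visual
  overlap 0 in brightness mode, 32x32 frames. The CNN learns the images
  (about 0.95); adding the uninformative mechanical branch must not change
  accuracy by more than 3 points.
* *Transfer*: the same-cell-line regime — tight diameters (14.2 +/- 1.5
  um), source stiffness 2 +/- 0.5 vs 5 +/- 1.0, target populations scaled
  by 1.25 (a chemically-stiffened-variant analogue: same morphology,
  shifted mechanics, near-ceiling separability). Fine-tuning the
  pretrained fused model on 10 cells (about 1/30 of the full target
  training examples) for 30 epochs must land within 5 points of a
  from-scratch model trained on the full target set.
* *Grad-CAM*: 128x128 frames with the cell filling roughly a third of the
  frame (the bounding-box-crop regime a detector would produce). At 64x64
  the final stage's 2x2 map has receptive fields spanning the entire
  frame and cannot localize anything — an architectural fact, not a bug.
  With the compact desk-scale encoder the *penultimate* stage's map is the
  sharper localizer (0.94 vs 0.88 inside-vs-outside success at 128x128);
  at full scale the ordering reverses and the last stage is the most
  focused, which is the regime the original observation describes.

Benchmarks use a compact encoder (8 base filters, one block per stage,
embedding width 64) so the whole suite trains more than twenty networks on
one CPU within minutes; the architecture audit checks the reference
configuration (64 base filters, two blocks per stage, embedding width 512,
fused latent 528) exactly.

## Known limitations

* The mechanics model is phenomenological: monotone in stiffness by
  construction, with no membrane bending resistance (`Kb` is carried but
  unused), no viscoelastic time constants beyond a single relaxation rate,
  and no hydrodynamic cell-wall interaction.
* The renderer's two texture cues are simplistic proxies for real
  morphological class differences.
* Only binary classification is supported; the checkpoint schema and fold
  plans assume two classes.
* Pure-R training is CPU-bound: the reference-width encoder is practical
  for auditing and small studies, not for large image corpora.
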