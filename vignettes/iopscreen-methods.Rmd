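---
title: "Methods: non-contact screening for elevated intraocular pressure at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-contact screening for elevated intraocular pressure at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(iopscreen)
```

## The problem

Applanation and air-puff tonometry estimate intraocular pressure (IOP) by
deforming the cornea, so the reading is confounded by corneal biomechanics —
most prominently central corneal thickness (CCT). `iopscreen` implements a
fully non-contact alternative: a binary screen for ocular hypertension
(IOP > 21 mmHg) that fuses anterior-segment Scheimpflug cross-sections with
six structural clinical attributes (pupil-center thickness, corneal-vertex
thickness, corneal volume, anterior chamber depth, anterior chamber volume,
corneal diameter). Age and IOP itself are deliberately excluded from the
clinical branch: IOP is the label source and must not leak.

Because the clinical cohort this pipeline was designed around is private, the
package ships a calibrated phantom generator as its data substrate. Every
quantitative claim the test suite makes is therefore a claim about the
phantom conditions, not about clinical data.

## The phantom generator

The generator emulates the reference cohort: 780 eyes, 680 normal / 100 high
IOP (12.8%), with class-conditional attribute means taken verbatim from the
published baseline table — including its physiologically odd rows (anterior
chamber depth 7.9 mm normal vs 2.5 mm high; corneal diameter ~3 mm). These
are configuration defaults, not re-interpretations; overriding them is one
argument away.

Per class, records are drawn from a truncated multivariate normal (a Gaussian
copula with normal marginals). The normal class is conditioned on
IOP <= 21 mmHg and the high class on IOP > 21 mmHg, so labels follow the
21 mmHg rule exactly by construction. Three pooled attribute–IOP Pearson
correlations are calibration targets: +0.41 (central thickness), −0.17
(chamber depth), −0.14 (chamber volume). The pooled correlation of a
two-class mixture decomposes into a within-class and a between-class-means
component, so the generator solves, in closed form, for the within-class
correlation that makes the pooled value hit the target given the class
means, class probability and within-class spreads.

Within-class standard deviations default to 10% of the pooled attribute
mean. For anterior chamber depth this base default makes the calibration
infeasible: the verbatim group means are so far apart that the between-class
component alone forces a pooled correlation near −0.86, and no admissible
within-class correlation can recover −0.17. The configuration therefore
widens an attribute's sd to the smallest value at which the target becomes
reachable with within-class correlation at most 0.8 in magnitude (keeping
the copula positive definite); for depth this lands near 47% of the pooled
mean. A consequence worth stating plainly: with mean 2.5 mm and sd ≈ 3.4 mm,
negative chamber depths occur in the high-IOP class. Depth is not constrained
positive by the record invariants, and the renderer clamps it at draw time;
readers should treat this as a property of emulating an internally
inconsistent printed table, not of eyes.

Images are stylised 64 × 64 cross-sections (224 × 224 available): a bright
corneal arc whose pixel thickness is an affine map of pupil-center thickness
(about 1 px per 10 µm at 64 px), a dark anterior-chamber wedge whose height
is an affine map of chamber depth, a mid-grey substrate below, additive
Gaussian speckle (sd 0.02), and a randomised arc pose (centre ±5%, radius
±15%, apex row ±3%). The pose jitter is the nuisance variation: it ensures
that band thickness and wedge height — which sit inside a known ground-truth
mask — are the only label-carrying image features, which is exactly what the
Grad-CAM attribution checks rely on. The generator does **not** emulate
specular reflexes, lens structures, device vignetting or real speckle
statistics; passing tests say nothing about those.

Artifact injection reproduces the failure modes of low-quality generated
images: corneal edge discontinuities (a blanked band gap), abnormally bright
saturated patches, patches of uniform texture noise, and Gaussian blur, each
with a magnitude in [0, 1] and `magnitude = 0` guaranteed to be the identity.

## Augmentation and the quality gate

A toy two-generator/two-discriminator cycle-consistent GAN (least-squares
adversarial loss, L1 cycle loss, weight 10) provides image-level
augmentation; the published source cites the standard formulation without
architecture details, so generators are three 3 × 3 convolutions with a
sigmoid output and discriminators one convolution plus global average
pooling, all trained with Adam at desk scale. A `classic` mode (flip,
±3 px translation, intensity jitter) produces augmented sets of identical
shape when adversarial training is beside the point; the canonical scale is
600 images per domain, 1200 total.

Generated images are gated by a Broad Learning System (BLS): `m` random
sigmoid feature nodes, `p` random sigmoid enhancement nodes stacked on them,
and a ridge-regression output layer solved in closed form,
`beta = (Z'Z + lambda I)^{-1} Z' y`. Node counts default to the published
1000/600 (tests use 200/100), lambda to 1e-2, and the decision threshold to
T = 0.7, boundary inclusive. Adding enhancement nodes is a Schur-complement
block update of the cached normal-equation inverse — numerically identical
to a full refit with the same random nodes, without retraining them.

Two design points the source leaves open:

* **Regression input.** The quality score of a generated image is defined
  against its corresponding source image, so the BLS regresses on the
  flattened 32 × 32 downsample of the absolute difference between the pair.
  This cancels the pose variation the pair shares and makes the score a
  function of what generation changed. Training targets are the Pearson
  correlation between image and reference mapped to [0, 1], scaled by
  (1 − artifact magnitude) for corrupted training samples — monotone in
  corruption by construction.
* **Ridge design matrix.** The standard BLS regresses on concatenated
  feature + enhancement nodes; an `enh_only` switch restricts it to
  enhancement nodes for readers of the stricter formulation.

The full gate combines the BLS score with a Canny-style geometric integrity
screen (Gaussian-smoothed Sobel edges; flags for missing contour, an
interior run of columns with no bright-band pixel, and saturated area above
0.5%): an image passes only if the score reaches T **and** no flag is
raised. The two screens are complementary — the score responds to global
corruption (blur, texture), the integrity screen to localised geometric
damage — and the gate's measured accuracy (≈0.97 on held-out phantoms)
substantially exceeds either alone.

## Image encoder

The encoder is a Swin-style windowed-attention transformer: 4 × 4 patch
embedding with a learnable absolute positional embedding, four stages with
patch merging between them (spatial side halves, channels double), pre-norm
blocks of window-based multi-head self-attention alternating with shifted
windows, GELU MLPs, and a linear head on globally averaged final-stage
tokens. Two implementation choices matter for trainability at this scale:
positional information is indispensable (without it the encoder can only
form spatial-statistics features, and training stalls near chance), and the
residual output projections (attention projection and second MLP layer)
start at zero so every block begins as the identity — together with
global-norm gradient clipping this removes the mid-training collapses a
small-data transformer is otherwise prone to. The reference geometry (224 px, embed 96,
depths (2,2,6,2), heads (3,6,12,24), window 7) is available; the tiny preset
(64 px, embed 24, depths (1,1,2,1), window 4, MLP ratio 2) is the desk-scale
default used by the tests. Window attention is implemented as masked full
attention over the token grid — exact and simplest at these token counts —
and a window larger than the grid degrades to global attention by design.

No pretrained weights are shipped. Transfer learning is exercised as
*phantom pretraining*: the backbone is trained (cross-entropy, AdamW, cosine
decay after one epoch of linear warmup, global-norm gradient clipping) on
QC-passed augmented images, with standard best-epoch checkpointing — by
validation accuracy when a held-out set is supplied, by training loss
otherwise. Checkpoint selection matters twice over at small scale: it makes
an occasional late-training instability harmless, and for attribution it
picks the best-generalising epoch rather than a memorising one (a memorising
encoder can reach a lower training loss yet attribute its decisions
diffusely, since positional shortcuts work on training images only).
Because this phase starts from random initialisation, every layer trains
during it — freezing layers is only meaningful once there is something
learned to preserve, so the freeze policy belongs to subsequent fine-tuning
stages. "Lower convolutional layers" is read structurally as the
patch-embedding projection plus stage 1; frozen parameters are bit-identical
after training, which the suite checks by identity.

All differentiable components run on a small reverse-mode autodiff core
included in the package; every operation's gradient is tested against
central finite differences, so trainings are exact-gradient, not
approximate.

## KAN fusion head

Pooled stage features (by default the final two stages, global-average
pooled and concatenated) form the image vector; the six clinical attributes
are standardized with training-split statistics. Both branches are
projected (tanh) to a common width of 8 — the source states no projection
width — and combined convexly with learnable modality weights, kept on the
simplex by a softmax reparameterisation of two free scalars. The fused
vector enters a Kolmogorov–Arnold layer: each edge carries a learnable
cubic B-spline with K = 16 coefficients on a fixed knot grid over [−3, 3]
(inputs clamped into the grid; clamping passes zero gradient outside), each
output node sums its edges, and outer weights scale each edge. A polynomial
edge basis exists as an option but is off by default. The fusion order is
project → fuse → KAN → 2-way logits.

The basis is evaluated by the Cox–de Boor recursion with its analytic
derivative (needed to backpropagate through spline inputs); tests verify
partition of unity to 1e-10, local support, and agreement with the
`splines::splineDesign` recursion as an independent oracle.

Adaptive grid refinement allocates a knot budget over image regions
proportionally to mean gradient magnitude, by proportional floors with the
remainder going to the highest-gradient regions — exact budget conservation,
monotone in regional gradient, uniform on constant images. The source
prints this rule as a gradient-norm argmin while describing the opposite in
text; the implementation follows the text (more gradient, more knots), whose
intent is unambiguous.

Head training minimises plain cross-entropy, the task loss of the published
head. A `class_weights = "balanced"` option (inverse class frequency) is
available for users who care more about minority-class recall than raw
accuracy: at the 87:13 imbalance the unweighted optimum for a weak feature
set is the majority-class rule, and the balanced head instead trades
accuracy for recall. The ablation harness runs the unweighted,
source-faithful configuration. Regularization follows the source:
an L1 penalty on the head weights added to the task loss, a dynamic dropout
rate p(t) = p0 / (1 + beta t) on the fused vector (p0 = 0.2, beta = 0.1),
and early stopping when validation accuracy has not improved (tolerance
1e-6 — strict float equality would never trigger) for 10 consecutive
epochs. The learning-rate schedule is cosine decay after linear warmup; the
source only states that the rate decays early.

## Evaluation harness

Splitting is stratified and patient-grouped: whole patients are assigned
greedily (largest first, seeded tie-break) per class to the subset with the
largest remaining deficit, at ratios 8:1:1. With one eye per patient this
reproduces 624/78/78 on 780 samples exactly. Metrics are accuracy,
precision, recall, F1, specificity and the Matthews correlation coefficient,
verified against a brute-force confusion-count oracle; the printed source
formula that conflates F1 with specificity is resolved as specificity =
TN/(TN+FP) and F1 = 2PR/(P+R), and MCC with a zero denominator is defined
as 0 so imbalanced suites stay total. Classical baselines (RBF-SVM, random
forest, logistic regression) run on the six standardized attributes under
stratified 5-fold cross-validation with median reporting. Both the held-out
test protocol and 5-fold CV are implemented, since the source reports both
without saying which produced its headline row.

The ablation harness compares, under identical splits and seeds:
`full` (pretrained backbone features + clinical branch), `image_only`
(pretrained backbone features alone) and `no_pretrain` (random-initialisation
backbone features alone). The source lists "single-modal, without
pre-training, multimodal baseline" without pinning the middle variant's
modalities; the assignment here is the only one consistent with the expected
ordering full ≥ image_only ≥ no_pretrain, because the verbatim baseline
table makes the clinical attributes alone nearly separating (corneal volume
differs by ≈ 3.7 within-class sd between classes), so any clinical-using
variant dominates image-only ones. On phantoms the expected check is the
*ordering*, never the published accuracy values, which belong to the private
clinical cohort. A property of the phantom worth knowing when reading the
ablation table: only corneal thickness and chamber depth are rendered into
the image, with within-class spreads that cap the image-only Bayes accuracy
well below the clinical branch's; at that ceiling the two image-only
variants often coincide at the majority-class operating point under plain
cross-entropy, so ties in the ordering are expected and legitimate.

## Grad-CAM attribution

Class-activation maps backpropagate a class logit to a stage's token
features; channel weights are spatial means of those gradients, and the
rectified weighted channel sum is reshaped to the token grid, bilinearly
upsampled and max-normalized (an identically zero map is returned as zero
rather than dividing by zero). The default stage is the deepest one whose
token grid side is at least 7 — at the 224 px reference geometry that is
the final stage (side 7), at 64 px it is stage 2 (side 8). The rationale is
geometric: a 4 × 4 or coarser map cannot resolve a band-plus-wedge region a
dozen pixels tall, and the in-mask attribution of even a perfectly focused
model saturates far below its fine-grid value. Against the phantom
ground-truth
band + wedge masks, the trained backbone's mean in-mask heatmap mass is
required to reach 60% — an artifact-level choice, not a clinical claim —
and to be no less than an untrained copy's.

## Problem sizes and numerical choices

The test suite and acceptance script use: cohorts of 60–800 phantoms at
64 × 64; BLS gates at m = 200, p = 100 trained on 400 phantoms; CycleGAN
runs of 10 images per domain for 3 epochs; ablation backbone pretraining on
400 augmented images (200 per domain) for 10 epochs at peak learning rate
1.5e-3 with validation-loss checkpointing, followed for the attribution
analysis by three epochs of freeze-and-fine-tune on 400 real training
images; fusion heads trained ≤ 25 epochs.
These sizes were chosen so a complete run is comfortable on a single CPU
while every behavioural claim (calibration, gating, ordering, attribution)
remains measurable. Tolerances: ridge/incremental-BLS fidelity 1e-8/1e-6;
B-spline partition of unity 1e-10; stochastic calibration checks ±0.05 on
correlations and ±2 points on the class fraction at n = 10000.

## Known limitations

* The phantom is stylised; no claim transfers to clinical Scheimpflug data.
* The CycleGAN is a toy: it demonstrates the training mechanics (decreasing
  cycle loss, exact set cardinality, provenance) but not generation quality.
* Pure-R training limits scale; the full 224-px reference configuration
  builds and runs but is not exercised by the default suite.
* The verbatim baseline table is internally inconsistent (see above); the
  generator prioritises the printed correlation targets and documents the
  consequences rather than silently re-interpreting the table.
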