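---
title: "Modelling hypomimia from elicited facial expressions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling hypomimia from elicited facial expressions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

Hypomimia — the "masked face" of Parkinson's disease — reduces both the
*amplitude* of facial expressions and the *speed* with which they are
produced. This package models the detection problem in three levels, each
building a different feature representation of the same elicited-expression
clips.

## Expression stage segmentation

Each clip carries a per-frame activation curve (a valence-like scalar). We
segment it into five stages: neutral, onset (the transition into the
expression), apex, offset (the transition out), and neutral again.
`detect_stages()` works on the absolute activation so positive (smile) and
negative (anger) valence are treated identically, and applies fixed
threshold rules:

* **apex** — first index attaining the maximum absolute activation
  (first-occurrence rule on plateaus);
* **onset / offset** — first/last crossing of 50% of the apex amplitude on
  the rising/falling side;
* **neutral** — last index before onset (first after offset) at or below
  10% of the apex amplitude, falling back to the clip ends.

How the original acquisition software's valence curve was thresholded into
stages is not specified anywhere we could follow, so the 50%/10% crossings
with first/last-occurrence tie-breaking are this package's fixed,
reproducible choice; both thresholds are arguments. Curves whose apex
amplitude falls below `min_amplitude` (default 0.05) raise a dedicated
degenerate-curve condition rather than returning arbitrary indices.
Whether the two "neutral" frames should be threshold-detected or simply the
clip ends is equally unspecified; we threshold-detect with clip-end
fallback. Indices are 1-based throughout the R API.

From the stages, `extract_sequence()` assembles the analysis units: single
stage frames, or the multi-frame sequences `NOnA` (neutral–onset–apex),
`AOffN` (apex–offset–neutral) and `NOnAOffN` (all five). A frame may serve
in several subsequences. At the reference cohort scale — 54 subjects, five
expressions each — the five-stage sequences contain 1350 frames.

## Backbones

Three architectures are implemented on a small, deterministic CPU
neural-network engine (im2col + GEMM convolutions, batch normalisation,
residual blocks, Adam; all randomness flows through R's RNG):

* **ResNet50** — the standard 50-layer bottleneck network (stem, stages of
  3/4/6/3 blocks, global average pooling, 1000-way decision layer);
  25,557,032 parameters (25.6M). Feature mode removes the decision layer
  and exposes the 2048-d pooled vector.
* **VGG-8** — eight 3×3 convolutions in four groups of two, 2×2 max-pooling
  and dropout after each group, then six fully-connected layers and an
  8-unit sigmoid AU head; 295,448 parameters in total.
* **ResNet-7** — seven basic residual blocks alternating between
  dimension-changing conv-blocks (convolutional shortcut) and identity
  blocks, starting with a conv-block, then global pooling and the 8-unit
  head; 366,626 parameters.

The published descriptions of the two compact models fix their layer
structure and total parameter counts but not their convolutional channel
widths, and the two constraints conflict if the six fully-connected widths
are taken literally as 1024…32: that dense chain alone costs 699,360
parameters, more than twice the published VGG-8 total. We therefore keep
the six-layer, width-halving *shape* of the FC stack but treat its top
width as a free structural parameter, and recover all free widths with
`search_channel_config()`: an exhaustive search over monotone
non-decreasing 4-stage channel plans (8–256) and candidate FC top widths
(32–1024) for a configuration whose **exact** total matches the published
count, with lexicographically-smallest tie-breaking. The defaults are
`(8, 13, 50, 107)` with FC stack `64…2` for VGG-8 and `(9, 15, 33, 171)`
for ResNet-7. Because the last FC layer of the recovered VGG-8 stack is
narrow, the VGG-8 *feature tap* is its 32-unit fully-connected layer (the
conventional width for this architecture family); ResNet50 and ResNet-7
are tapped after global pooling. The tap is recorded on the model.

A randomly initialised residual backbone has batch-norm running statistics
at their 0/1 initialisation, which bears no relation to the data; before
using such a backbone as a feature extractor, `calibrate_bn()` runs a few
forward passes over rendered calibration faces to set the buffers (weights
are untouched). Training performs the same adaptation implicitly. A loader
hook (`load_model()`) accepts an externally trained checkpoint; all tests
run from random initialisation — the framework, not any pretrained weight
set, is what is under test.

## Action-unit adaptation by layer freezing

`freeze_layers(model, fraction)` freezes the first ⌈fraction·L⌉
parameter-bearing layers in forward order (within a residual block the main
path precedes the shortcut); the attached head is always trainable, so
`fraction = 1` is the frozen-backbone baseline. The source framework
reports 20.5M/16.0M trainable parameters for its 50%/75% freezing of
ResNet50, figures that no prefix boundary reproduces exactly under either a
module-wise or a Keras-style layer enumeration (the nearest achievable
counts are ≈20.4M and ≈16.5M); `calibrated_freeze_boundary()` therefore
selects, once per fraction, the boundary minimising the distance to the
reported count, and the freeze plan records the resulting numbers.

Training (`train_au()`) minimises per-AU sigmoid binary cross-entropy
averaged over AUs and images — the adaptation task is the detection of AUs
1, 2, 4, 5, 6, 12, 25 and 26, the units underlying the anger (4, 5, 25,
26), smile (6, 12, 25) and surprise (1, 2, 5, 25, 26) tasks. Optimiser
settings are unspecified in the source description, so the defaults are
Adam, learning rate 1e-3, 30 epochs, batch 32, early stopping with
patience 5 on validation loss, and ±10° random-rotation augmentation; all
are arguments. Frozen batch-norm runs in inference mode, which makes the
frozen prefix a fixed function — its activations are precomputed once per
dataset when augmentation is off, which is what makes CPU training of the
frozen variants cheap. AU detection is evaluated with per-AU ROC-AUC and
the equal error rate; `compute_eer()` interpolates linearly between the
two thresholds straddling the FPR = FNR crossing, a rule fixed here
because it is deterministic and checkable against an exhaustive threshold
scan.

## Triplet embeddings

The Parkinson-domain representation is learned with the hinge triplet loss
over the Mahalanobis-form squared distance
`d²(x_i, x_j) = (x_i − x_j)ᵀ M (x_i − x_j)` with `M = TᵀT` positive
semi-definite — equivalently `‖T x_i − T x_j‖²`, generalised to a network
embedding Φ. Valid triplets pair an anchor with a positive of the *same
class but a different expression* and a negative of the other class;
`mine_triplets()` either enumerates the full valid set or draws uniformly
from it (seeded). Design choices left open by the source description,
resolved here and all configurable:

* margin α = 0.2 (standard for normalised embeddings) — α is not stated
  anywhere we could follow;
* embedding dimension 128, L2-normalised before distances (normalisation
  recorded on the transform);
* anchor and positive may come from different subjects; a
  `same_subject_positives` flag restricts mining when set;
* training uses fresh uniformly-drawn valid triplets per epoch rather than
  hard-negative mining, which the source framework does not describe;
* whether the frozen-backbone triplet variants retrain the whole unfrozen
  tail or only a final linear map is unspecified: both are implemented
  (`network_phi`, the default, and `linear_T`), and for freeze-derived
  models the frozen layers stay frozen during triplet training.

## Classification protocol

Sequences are fused either by concatenating the per-frame feature vectors
in temporal order (default) or by averaging per-frame SVM scores at
decision time (`mean_score`); the source description mentions both
feature-level and score fusion without fixing one, so both are implemented
and every report is stamped with the mode. Classification uses SVMs over
the fixed grid C ∈ {10⁻⁴…10³} (8 points) for both kernels and
γ ∈ {10⁻⁴…10³} for the Gaussian kernel — 64 Gaussian + 8 linear
configurations — under nested 5-fold subject-independent cross-validation:
subjects are split into stratified outer test folds; the remaining
subjects split 80/20 into train and validation; the configuration with the
best validation accuracy (ties towards the canonical grid order) is refit
on train+validation and evaluated on the test subjects. Since 54 is not
divisible by 5, outer folds hold 11/11/11/11/10 subjects and per-fold
sample counts vary; the suite checks conservation (fold totals sum to the
cohort) rather than any fixed per-fold size. A subject-leakage audit runs
on every cross-validation call. Hyper-parameters are reported per fold and
summarised by their mode (ties towards smaller C, then smaller γ). The
decision threshold is 0 on the signed decision score; AUC uses the
continuous score; PD is the positive class. Internally the grid search
runs on per-fold precomputed Gram/distance matrices, so the 72-point grid
costs little more than a single fit.

Model comparison (`compare_models()`) runs 25 re-seeded cross-validations
per model with fixed hyper-parameters, then a Kruskal–Wallis test across
models and pairwise Mann–Whitney U tests at the Bonferroni-corrected level
α_cor = 0.05/number-of-pairs (0.05/3 ≈ 1.66e-2 for three models).

# The synthetic cohort generator

Real corpora of this kind are private, so the generator is a first-class,
tested component. It emulates the *structure* of such a corpus: `n_pd + n_hc`
subjects (reference scale 30 + 24), five tasks per subject (right eye wink,
left eye wink, smile, anger, surprise), ~6-second clips at 15 frames/s.

**Activation curves.** Each clip's curve is a trapezoid — baseline, linear
rise, apex plateau (1.2 s), linear fall — plus Gaussian jitter. Severity
`s ∈ [0, 1]` drives the hypomimia phenotype: apex amplitude
`A0·(1 − β·s)` and 10→90% rise time `τ0·(1 + γ·s)`. Defaults: `A0 = 0.9`,
`β = 0.5`, `γ = 1.0`, jitter σ = 0.02, `τ0 = 0.5 s`; patient severities
are drawn from Uniform(0.4, 1). These constants produce a learnable but
non-trivial class separation: amplitude distributions overlap once
individual expressivity differences are added, while the slowed onset
remains. How the acquisition software's valence behaves for winks is
unknown; we use the same activation-magnitude semantics for all five tasks
and note the divergence.

**Faces.** Frames are procedural 2-D grayscale renderings: a smooth head
ellipse with brows, eyes, cheeks and mouth whose geometry is driven by ten
unitless movement parameters covering the eight AUs (brow raisers/lowerer,
lid raiser, cheek raiser, lip-corner puller, lips part, jaw drop, per-eye
closure). Rendering is a pure function of the parameters, the image size
and a per-subject identity; the default size is 64×64 (32×32 for the
reduced-scale runs), and eye proportions are chosen so lid movements stay
legible at 32 px. Each expression maps its activation value onto a fixed
AU-consistent parameter profile (e.g. smile → lip-corner pull, cheek
raise, slight lips part). `au_labels_for()` sets an AU bit iff the AU
belongs to the expression's group *and* the absolute activation reaches
the on-threshold (default 0.5 of full activation, which yields balanced
positive rates in the AU dataset).

**Inter-subject variability.** Face corpora vary far more across
identities than across expressions, so each subject draws: facial geometry
(head proportions ±10%, eye spacing/size, brow and mouth position, skin
tone), an individual expressivity multiplier (truncated normal, sd 0.12)
on the apex amplitude, and a tempo multiplier (±15%) on the rise time —
applied to both groups, with severity effects on top. A per-subject pixel
texture field (sd 0.02) and per-frame sensor noise (sd 0.01) complete the
identity model. `subject_variability` scales all of this; 0 produces
identical template subjects, which is how the suite constructs an
explicitly separable cohort for pipeline sanity checks. These magnitudes
are one-time realism choices: they make single apex frames genuinely
ambiguous (identity swamps amplitude, as with real identity-trained face
features) while leaving the neutral-referenced sequence information
intact.

**What passing tests do and do not show.** The generator reproduces the
*structure* of the problem — elicited dynamics, AU semantics, identity
nuisance, subject-level sampling — but not photorealistic appearance, head
pose, tremor, lighting, or the correlation structure of real facial
musculature. Directional results on synthetic cohorts (sequences beat apex
frames; AU adaptation beats a frozen backbone; triplet training beats a
random embedding) demonstrate that the pipeline recovers signals it is
pointed at, not that it attains any particular accuracy on clinical data;
the published clinical accuracies are not reproducible without the
private corpus and are not asserted anywhere in the suite.

# Numerical and engineering choices

* All generators and training loops are pure functions of their arguments
  and a seed; child seeds are derived deterministically and stay below
  2³¹. Evaluation-mode forwards are deterministic.
* The EER linear-interpolation rule, the first-occurrence apex tie-break,
  the first-best grid tie-break and the smallest-C mode tie-break are all
  fixed so every reported number is reproducible and oracle-checkable.
* Degenerate inputs fail loudly with dedicated condition classes
  (validation errors, degenerate curves, infeasible architecture
  searches); single-class AUs are flagged as undefined rather than
  dropped; single-class test folds are excluded from averages with a
  warning.
* Feature standardisation uses fitting-set statistics only; zero-variance
  dimensions get unit scale.
* Reduced problem sizes used by the test suite (12-subject cohorts, 32 px
  renders, 240-image AU sets, 5 training epochs, 8 triplet epochs with 128
  triplets, embedding dimension 32) are the package's reduced-scale
  configuration (`smoke_config()`); the statistical conditions — hypomimia
  constants, grids, fold structure — are identical to the study-scale
  defaults.

# Known limitations

* The CPU engine is sized for these networks; it does not implement GPU
  execution, weight decay, or learning-rate schedules.
* ResNet50 variants with squeeze-excitation blocks, and face
  detection/alignment on raw video, are out of scope; the package consumes
  activation curves rather than re-deriving them from pixels.
* The published trainable-parameter counts for the frozen variants cannot
  be met exactly by any layer boundary (see the freezing section); the
  calibrated boundaries and their actual counts are recorded in every
  freeze plan.
* With random initialisation the face-analysis backbone is a random
  projection, so absolute accuracies at reduced scale are far below the
  published clinical figures — only directions and protocol properties are
  meaningful at that scale.
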