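---
title: "Methods: three-stage ensemble screening of fetal genetic disorders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three-stage ensemble screening of fetal genetic disorders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fgscreen)
```

## The screening problem

Chromosomal disorders (trisomy 21/18/13 and rarer syndromes) often manifest
as subtle facial dysmorphology visible in the midsagittal fetal-profile
ultrasound plane: increased nuchal translucency (NT), an absent or
hypoplastic nasal bone, and altered chin/jaw contours. `fgscreen` implements
a three-stage ensemble that turns one profile image into a disorder
probability:

1. **Network A** — a single-stage anchor-based detector localizes seven
   anatomical regions of interest (ROIs): `Chin`, `head1`, `head2`, `D`
   (diencephalon), `NA + NB` (nasal apex + nasal bone), `max + mand`
   (maxilla + mandible) and `NT`. Formally `R = A(I)`.
2. **Network B** — per-ROI residual CNNs score each detected region against
   the image-level disorder label, `s_i = B(r_i)`. The diencephalon is
   detected as a landmark but excluded from risk scoring: it carries no
   screening information.
3. **Network C** — gradient-boosted trees stack the six risk values into the
   final probability, `P = C(S)`, exploiting interactions between regions.

Grad-CAM heatmaps over each ROI crop expose which sub-regions drive each
risk score.

## Preprocessing

Ultrasound images carry a smooth multiplicative illumination field (gain,
coupling, depth attenuation). The homomorphic filter removes it:
`exp(IFFT(H · FFT(log(I + eps))))` with a Gaussian-shaped high-emphasis
transfer function rising from `gamma_low` at DC to `gamma_high` above the
cutoff. No published parameterization exists for this application, so the
defaults are the standard textbook high-emphasis configuration —
`gamma_low = 0.5`, `gamma_high = 1.5`, cutoff `30/512` of the spectrum
radius, unit slope, `eps = 1e-3` — all exposed in the config. Filtering is
applied once per image, before detection; ROI crops are taken from the
filtered image. Outputs are min-max rescaled to [0, 1]; constant images are
returned unchanged (there is no illumination gradient to remove).

Crops and detector inputs are letterboxed: one scalar scale preserving the
aspect ratio exactly, symmetric padding with 114/255 (the common detector
convention), and an invertible transform record so detections map back to
original coordinates within half a pixel.

## The neural operators

All neural computation runs on the package's own compact CNN engine: a
tape-based reverse-mode autodiff over `(channels, height, width)` arrays
with im2col+GEMM convolutions in C++ and exact analytic gradients (verified
against finite differences in the test suite). The operators are also
exposed as standalone forward functions on plain arrays, each checked
against an independent scalar-loop oracle:

* **Fast-normalized fusion** (the BiFPN fusion rule):
  `O = sum_i w_i / (eps + sum_j w_j) · I_i`, `eps = 1e-4`, with raw weights
  projected non-negative (ReLU) before use. The coefficients sum to
  `sum(w)/(eps + sum(w)) ∈ [0, 1)`; an all-zero weight vector legitimately
  produces the zero map.
* **BiFPN node**: the intermediate (top-down) path fuses exactly two inputs
  and the output (bottom-up) path exactly three, each followed by a 3×3
  convolution; cross-level `Resize` is nearest-neighbour by a factor of 2
  (the conventional choice; nothing in the method constrains it).
* **ECA (efficient channel attention)**: implemented in its printed
  fully-connected form — `W = FC(ReLU(FC(AvgPool(X))))`, `Y = X ⊙ W`,
  `Z = Y · γ` — rather than the 1-D-convolution design of the cited
  attention module; the conventional form is available via
  `eca_variant = "conv1d"`. Two numerical choices were open: the printed
  equations omit a squashing function, so a sigmoid is inserted after the
  second FC (without it the channel weights are unbounded and element-wise
  gating loses its attention semantics), and the output scale γ (no stated
  initialization or constraint) starts at 1.0 as a learnable scalar.
* **CBAM**: channel attention is a reduction-16 FC pair with sigmoid;
  spatial attention follows the printed form — an FC on the globally
  max-pooled channel vector of the gated map, which makes it a second
  channel gate — with the canonical 7×7-convolution spatial map one flag
  away (`sam_variant = "conv7x7"`). With all gate weights zero both factors
  are exactly σ(0) = 0.5, so the block reduces to a 0.25 scaling; this limit
  anchors the compositional tests.
* **Residual connection**: `Y = X + F(X)`, with a 1×1 projection on the
  shortcut when the shape changes.

## Network A: the detector

The method's contribution is the neck (BiFPN) and the attention (ECA); the
backbone is unspecified, so the package uses a small strided conv backbone
(channel plan 8/16/32/48/64, leaky ReLU) with ECA after each stage feeding
the neck, a width-16 BiFPN, and per-level heads predicting box offsets,
objectness and 7 class scores for 3 anchors per level. Both a 3-level
(strides 8/16/32) and a 5-level (adds 64/128) pyramid are available; the
desk-scale studies use the tiny 3-level variant at 128 px input.

Training uses the standard single-stage recipe: CIoU box loss on matched
anchors (gradients of the CIoU term are taken by central differences in the
four decoded box coordinates and chained analytically through the
sigmoid/exp decoding — 8 extra CIoU evaluations per matched box, which is
negligible), BCE objectness, and BCE class scores. Matching assigns each
ground-truth box to its best shape-IoU anchor (aspect-ratio gate 4) plus any
anchor with shape IoU ≥ 0.5. Two choices matter for convergence without
batch normalization: objectness positives and negatives are normalized
separately (the handful of positive cells would otherwise be drowned by
~1000 background positions), and the objectness bias starts at −3 (a
background prior). Flips are disabled throughout — facial-profile chirality
is anatomically meaningful.

Inference filters by objectness × class probability, applies per-class
greedy NMS (IoU 0.45, ties broken by lowest `x_min` for determinism), and
maps boxes back through the letterbox transform.

## Network B: per-ROI classifiers

Two architectures, both on 256×256 letterboxed grayscale crops with a single
sigmoid logit:

* **CNN A** (complex ROIs — default `Chin`, `NA + NB`, `max + mand`,
  `head2`): 7×7 stem, residual stages of 3/4/6/3 two-conv blocks — 34
  weighted layers on the main path — with CBAM after each stage. The exact
  per-layer table of the original design is not published; the stage plan is
  the standard 34-layer residual plan, and CBAM placement after each stage
  is the package's choice.
* **CNN B** (simple markers — default `NT`, `head1`, covering NT thickness
  and the cranial vault): 7×7 stem, three two-conv residual blocks, one
  CBAM before pooling — exactly 8 weighted layers on the main path.

The assignment is configurable; which cranial region feeds which network is
not determinable from the method description, so `head1` (cranial vault)
goes to CNN B and `head2` to CNN A.

There is no batch normalization in the engine; two choices replace it. The
second convolution of every residual block is zero-initialized, so each
network starts as a near-identity chain of projections and remains
optimizable at depth 34; and all stem/block activations are leaky ReLU
(slope 0.1) — with plain ReLU the narrow reduced-width stages can
irrecoverably die into a constant-output attractor within an epoch.
Gradient steps are additionally global-norm clipped. Training minimizes BCE with Adam, samples batches 1:1 from the
two classes (positives are the minority at the default prevalence), applies
Trivial Augment to training crops only, and keeps the best
validation-AUC parameters. Classifiers train on ground-truth crops; at
inference they consume detector crops.

CNN A's channel plan is 64/128/256/512 × `width_mult`. The desk-scale
default is `width_mult = 0.0625` (plan 4/8/16/32), which keeps a 34-layer
forward/backward pass at roughly the cost of CNN B.

## Trivial Augment

One operation drawn uniformly per sample, one strength drawn uniformly from
the operation's range. The operation set is the canonical list minus
colour-space operations (grayscale input) and minus horizontal flip
(chirality): identity, rotation (±15°), x/y translation (±10 %), x/y shear
(±0.15), brightness (±0.2), contrast (0.7–1.3), sharpness (0–1), histogram
equalization, posterize (4–8 bits). Geometric fills use the letterbox value.
The original operation magnitudes are not published for this application;
these bounds are conservative crop-safe choices.

## Network C: stacking

The six sigmoid probabilities (one scalar per ROI — the "last layer output"
convention; penultimate-embedding stacking is out of scope) are stacked by
xgboost with logistic loss: up to 200 trees, depth 3, learning rate 0.1,
subsample 0.8 — shallow trees suit a 6-dimensional feature space. The
actual number of boosting rounds is chosen by 5-fold cross-validated early
stopping under the 200-round cap: stacking folds are small (a few hundred
rows), and a fixed deep ensemble measurably overfits the no-signal risk
features there, diluting the strongest ROI instead of adding to it. Missing
risks (detector misses) default to the `indicator` policy: probability set
to 0.5 plus six missingness indicators, so silent detector failures cannot
bias the stacker; `impute_mean` and xgboost-`native` NA handling are
alternatives. Optional per-feature monotone constraints make `P`
non-decreasing in every risk.

The stacker trains **out of fold**: Network B trains on the training split;
the risk vectors that train Network C come from running the full
detector→classifier path on the validation split. The original description
says only that the stages train separately; without this protocol the
stacker would inherit the classifiers' training optimism.

The decision threshold is chosen on validation data only: fixed 0.5, or the
Youden point (maximizing sensitivity + specificity − 1) over thresholds
midway between consecutive unique scores.

## Grad-CAM

Channel weights are spatial means of ∂(positive logit)/∂(feature map);
the heatmap is `ReLU(Σ_c w_c A_c)`, bilinearly upsampled and max-normalized
(skipped when identically zero). The default target is the last
convolutional map before pooling, the conventional choice (the original
figure does not name its layer). Heatmaps are computed per ROI crop, not on
the full image.

Localization is verified two ways: a constructed model whose logit is the
mean of a fixed image quadrant (realized as a fixed spatial mask followed by
a convolution, so the target layer's activations — and hence the heat — are
confined to the quadrant), and the trained NT classifier's heat mass inside
the planted NT band, which must exceed the band's area fraction on positive
phantoms.

## Metrics

Confusion-matrix metrics with the usual definitions; undefined ratios are
reported as NaN with a note, never silently zero. Wilson score intervals at
95 % for sensitivity/specificity (the interval method behind the
parenthesized ranges in clinical tables is typically unstated; Wilson is the
robust default and is config-exposed). ROC/AUC by trapezoidal integration
over unique thresholds, which equals the normalized Mann–Whitney statistic
under ties. Detection AP uses all-points interpolation with greedy
confidence-ordered one-match-per-truth assignment, the modern detector
convention.

## The phantom generator

Clinical fetal-ultrasound collections are not redistributable, so every
stage is exercised on synthetic phantoms: a speckle-textured head-and-face
silhouette on a dark background with seven planted ROI structures in a fixed
anatomically plausible arrangement (cranial arcs, a diencephalon blob, a
nasal streak, jaw bars, a chin contour arc, a dark NT band between bright
skin lines), jittered per image by ±5 % of the image side in position and
±10 % in scale. Speckle is first-order multiplicative Rayleigh noise on the
silhouette followed by a 1-px Gaussian blur; a smooth low-frequency cosine
illumination field multiplies the image last. `(seed, index)` fully
determines a phantom; the generator records hidden ground truth (band
masks, planted parameter values) for oracle tests, which the pipeline never
reads.

Label signal is planted only in configured ROIs: by default the NT band is
1.5× thicker in positives, the nasal-bone streak is dimmed to 0.4 of its
amplitude (absent nasal bone), and the chin arc curvature increases 1.4×;
the evaluation study uses the two-signal variant (NT + nasal bone). All
other ROIs are pixel-identical across labels given the same noise draw, so
a classifier trained on them can only reach chance AUC — the
signal-isolation null that the tests assert.

What the phantoms do **not** emulate: real anatomical shape variation,
gestational-age dependence, probe-specific scan-conversion geometry, shadows
and reverberation artifacts, or inter-operator variability. Passing tests
therefore demonstrate that the machinery — detection, per-ROI risk
extraction, stacking, attribution — recovers planted signal through the
full pipeline; they say nothing about clinical performance, whose headline
numbers require the original patient data. One visible consequence: the NT
marker, which is geometrically explicit here, saturates near AUC 1.0 in the
synthetic regime, above the 0.85-class AUC such markers reach clinically;
the nasal-bone dimming (AUC ≈ 0.75–0.9) and chin curvature (weaker) land
inside the clinically typical range.

## Study sizes and reproducibility

The bundled evaluation study runs on one CPU at desk scale: 280/100/160
train/validation/test phantoms for the main (noisy, two-signal) study,
200/50 for the easy (noise-free) detector study with its label-shuffled
negative control, 20 epochs for the easy detector, 10 for the main one,
4/3/2 classifier epochs for signal/nasal/no-signal ROIs. Every random
procedure derives its seed from one master seed, so a study run is exactly
reproducible:

```{r}
res <- run_evaluation_study(seed = 1, work_dir = tempdir())
```

A note on the easy detector study: the negative control retrains the
detector on annotation files decoupled from their images. With no geometric
jitter this control would be vacuous — every phantom would carry identical
boxes and shuffling would change nothing — so the "easy" condition removes
noise (speckle and illumination) but keeps the standard jitter.

## Known limitations

* The engine is single-threaded and desk-scale; it is a faithful
  implementation, not a performance-competitive trainer.
* No batch normalization; the zero-init residual scheme is the stabilizer.
* The detector's 5-level variant and the canonical ECA/CBAM forms are
  implemented and unit-tested but not exercised by the default study.
* Binary screening only — the pipeline does not type syndromes, mirroring
  the stated scope of the method it implements.
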