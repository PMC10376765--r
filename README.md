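# fgscreen

Three-stage ensemble screening of fetal genetic disorders from midsagittal
fetal-profile ultrasound images, in R.

Chromosomal disorders (trisomy 21/18/13 and rarer syndromes) leave subtle
marks on the fetal face that are visible in the midsagittal ultrasound
plane: a thickened nuchal translucency (NT), an absent or hypoplastic nasal
bone, altered chin and jaw contours. `fgscreen` is for researchers in
prenatal imaging and medical image analysis who want a complete, inspectable
implementation of a region-of-interest ensemble screening pipeline — every
stage trainable and testable on synthetic phantoms, with no patient data
required.

## The model

One profile image `I` is screened in three stages:

1. **Network A — ROI detection.** `R = A(I)`: a single-stage anchor-based
   detector with a BiFPN feature-fusion neck and efficient channel attention
   (ECA) localizes seven anatomical ROIs (`Chin`, `head1`, `head2`, `D`,
   `NA + NB`, `max + mand`, `NT`). BiFPN nodes combine feature maps with
   fast-normalized weighted fusion

   O = Σᵢ wᵢ / (ε + Σⱼ wⱼ) · Iᵢ,  wᵢ ≥ 0, ε = 10⁻⁴.

2. **Network B — per-ROI risk.** `sᵢ = B(rᵢ)`: each risk ROI (all but the
   diencephalon `D`) is letterboxed to 256×256 and scored by its own
   residual CNN with convolutional block attention (CBAM) — a 34-layer
   network for complex regions (chin, nose/jaw, cranium) and an 8-layer
   network for simple markers (NT thickness, cranial vault) — trained with
   Trivial Augment against the image-level disorder label.

3. **Network C — stacking.** `P = C(S)`: gradient-boosted trees (xgboost)
   map the six risk values (plus missingness indicators) to the final
   disorder probability, trained out-of-fold on validation risk vectors.

Images are illumination-corrected by homomorphic filtering before
detection; Grad-CAM heatmaps over each ROI crop show which sub-regions
drive each risk score. All neural operators run on the package's built-in
CNN engine (tape autodiff over `(C, H, W)` arrays, im2col convolutions in
C++, exact gradients), and each printed operator — fusion, ECA, CBAM,
residual — is unit-tested against an independent scalar-loop oracle.

Because clinical fetal ultrasound collections are not redistributable, the
package ships a synthetic phantom generator: speckle-textured profile
silhouettes under a smooth multiplicative illumination field, seven planted
ROI structures with anatomically plausible layout and per-image jitter, and
label-dependent morphology in a configurable subset of ROIs (NT band
thickness, nasal-bone streak amplitude, chin curvature). Non-signal ROIs
are pixel-identical across labels, giving exact negative controls. See
`vignette("fgscreen-methods")` for the full model description and design
rationale.

## Worked example

A miniature end-to-end run (150 training phantoms, a few minutes on one
CPU):

```r
library(fgscreen)

# a 2-signal phantom population: NT band 1.5x thicker in positives,
# nasal-bone streak dimmed to 0.4
spec <- study_phantom_spec(seed = 1)
train <- generate_dataset(spec, 150, "phantoms/train", splits = c(train = 1))
val   <- generate_dataset(study_phantom_spec(seed = 2), 60, "phantoms/val",
                          splits = c(val = 1))

bundle <- fit_pipeline(train, val,
                       det_config = detector_config(epochs = 12),
                       clf_config = roi_classifier_config(epochs = 3))

img <- png::readPNG(train$image_files[1])   # a positive phantom
pred <- run_pipeline(img, bundle, explain = TRUE, explain_rois = "NT")
pred$probability
#> [1] 0.409
round(pred$risk_vector$s, 3)
#>       Chin      head1      head2    NA + NB max + mand         NT
#>      0.502      0.499      0.500      0.544      0.501      0.996
```

`risk_vector$s` holds the per-ROI probabilities `sᵢ`: the no-signal ROIs
sit at chance (~0.5) while the NT classifier fires at 0.996 on this
positive phantom — on a negative phantom from the same run it reads 0.034.
`pred$probability` is the stacked estimate `P`; at this miniature
stacking-fold size its calibration is coarse (0.409 here vs 0.293 on the
negative) although the ranking already separates the classes.
`pred$heatmaps$NT` is the Grad-CAM map over the NT crop, renderable with
`render_overlay()`.

The full desk-scale study — easy-set detector with a label-shuffled
negative control, per-ROI signal recovery, stacking, end-to-end
evaluation — is one call:

```r
res <- run_evaluation_study(seed = 1)
res$detector_map_easy    # 0.997   mAP@0.5 on 50 held-out easy phantoms
res$auc_nt               # 0.984   NT classifier AUC, 160-phantom test split
res$auc_nonsignal_head1  # 0.509   no-signal ROI stays at chance
res$end_to_end_auc       # 0.9985  full-pipeline AUC on the test split
```

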