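# hyperseg

Multi-label 3D segmentation of the **left atrium (LA)** and the
**epicardial adipose tissue (EAT)** surrounding it from Dixon-style
cardiac MRI, using a U-Net whose encoder carries a parallel
**hyperbolic (Poincaré-ball) branch** with learnable curvature and a
hyperbolic multinomial logistic regression head.

EAT — the fat depot between the myocardium and the pericardium — is a
risk factor in atrial fibrillation, but it is a thin, patchy, severely
under-represented structure (a few mL against litres of field of view).
The package implements a two-stage pipeline for Dixon acquisitions,
which yield separated water and fat images plus a fat-fraction map
`FF = fat / (fat + water)`:

1. **Stage 1** — a plain 3D U-Net localizes a region of interest on the
   fat image.
2. **Stage 2** — on the cropped water/fat/fat-fraction channels, a U-Net
   whose encoder blocks compute a Euclidean branch `F_e = σ(X∗W + b)`
   and a hyperbolic branch `F_h = W ⊛ exp₀(F_e)` (Möbius convolution of
   the Poincaré embedding), concatenated and downsampled, classifies
   every voxel into {background, LA, EAT}.

## The geometry

All hyperbolic computation lives on the Poincaré ball of curvature `k`,
`{p : k‖p‖² < 1}`, with conformal factor `λ_p = 2/(1 − k‖p‖²)`:

* **Möbius addition** `q₁ ⊕ q₂` (the gyrogroup sum) and Möbius scalar
  multiplication;
* **exp/log maps** `exp_P(v) = P ⊕ (tanh(√k λ_P ‖v‖/2) v/(√k‖v‖))` and
  its inverse, used to move features between Euclidean (tangent) space
  and the ball;
* the **HMLR head**: per class `y`, a plane on the ball (offset `p_y`,
  normal `a_y`, scale `ζ_y`) gives each voxel feature `z` the logit
  `ζ_y λ_{p_y} ‖a_y‖ / √k · asinh( 2√k⟨(−p_y)⊕z, a_y⟩ /
  ((1 − k‖(−p_y)⊕z‖²)‖a_y‖) )`, softmaxed into posteriors;
* the **curvature is learned** through `k = e^{l_k σ} + l₀` (floor
  `l₀ = 10⁻³`), and manifold parameters (plane offsets, Möbius bias
  points) are updated by **Riemannian SGD**
  `p ← exp_p(−lr · g (1 − k‖p‖²)²)`.

Training minimizes the composite loss

```
L = 0.5·L_CE + 0.2·L_curvature + 0.5·L_IDWH + 0.2·L_weights
```

where `L_CE` is inverse-prevalence-weighted cross-entropy, `L_IDWH` is a
Dice-form loss whose per-voxel weights `1/(1+d)` decay with the distance
`d` (mm) to the LA boundary — concentrating the loss on the EAT rind —
and the remaining terms regularize the curvature (log-space quadratic)
and the Euclidean weights (L2). Class imbalance is additionally handled
by balanced patch sampling (patch centers alternate between EAT, LA and
background voxels) and flip/rotation/scaling augmentation.

Since no deep-learning framework exists in this R stack, the 3D
convolutions, pooling, upsampling and Euclidean distance transforms are
compiled Rcpp/RcppArmadillo kernels, and every layer — including all
hyperbolic operations — carries a hand-derived analytic backward pass
validated against finite differences in the test suite.

The package also ships a **synthetic Dixon phantom generator**
(ellipsoidal LA blood pool, thin wall, patchy high-fat EAT rind,
distractor fat blobs, Gaussian noise, fat fraction recomputed from the
noisy channels), the **semi-automatic EAT ground-truth pipeline**
(fat-fraction normalization, strict 0.4 threshold, manual-ROI
intersection), segmentation/volumetry **metrics** (Dice, IoU,
precision/recall/F1, Hausdorff and average symmetric surface distance in
mm, volumes in mL, Pearson and Bland–Altman agreement), and minimal
**NIfTI-1 I/O** — so the whole pipeline is testable without clinical
data.

## Worked example

```r
library(hyperseg)

# 1. simulate a small cohort of Dixon phantoms (48^3, 1.25x1.25x2.5 mm)
cfg   <- phantom_config(shape = c(48, 48, 48))
train <- generate_dataset(8, cfg, seed = 11)
test  <- generate_dataset(2, cfg, seed = 99)

# 2. train the stage-2 hyperbolic network on balanced 24^3 patches
tcfg <- train_config(epochs = 12, batch_size = 2, euclid_lr = 0.02,
                     patch_size = 24, seed = 5,
                     model = model_config(base_channels = 8, depth = 3,
                                          patch_size = 24))
fit <- train_model(2, train, tcfg)
tail(fit$log[, c("epoch", "loss", "val_dice", "k")], 3)
#>    epoch       loss  val_dice         k
#> 10    10 0.11482181 0.8509609 0.9712990
#> 11    11 0.09810845 0.8554492 0.9706306
#> 12    12 0.09378208 0.8581957 0.9709986

# 3. segment a held-out phantom with an oracle ROI and score it
ph   <- test[[1]]
roi  <- array(as.integer(ph$labels$labels > 0), dim(ph$labels$labels))
pred <- two_stage_predict(ph$volume, roi, fit$model, margin = 8)
metric_report(pred, ph$labels)
#>      class      dice       iou precision    recall        f1        hd
#> LA      LA 0.9505864 0.9058263 0.9388530 0.9626168 0.9505864  2.795085
#> EAT    EAT 0.7802367 0.6396624 0.6571305 0.9601013 0.7802367 28.062430
#> mean  mean 0.8654116 0.7727444 0.7979917 0.9613591 0.8654116 15.428758
#>           assd volume_ml_pred volume_ml_truth
#> LA   0.4747492      20.570312       20.062500
#> EAT  2.2236798       9.011719        6.167969
#> mean 1.3492145      14.791016       13.115234
```

Reading the report: after 12 epochs (about a minute of training) the
model segments the LA blood pool + wall almost perfectly (Dice 0.95,
ASSD 0.47 mm) and recovers the thin EAT rind with Dice 0.78 — high
recall (0.96) but over-inclusive (precision 0.66, predicted EAT volume
9.0 mL vs 6.2 mL truth), the typical behaviour of a briefly trained
model on the minority class. `loss` is the composite objective above;
`k` is the learned ball curvature, drifting from its initial 1.001 as
training shapes the embedding. Longer training (the acceptance test uses
18 epochs on 16 phantoms) pushes mean foreground Dice above 0.9.

A command-line surface wraps the same steps:

```sh
Rscript inst/exec/hyperseg simulate --n 8 --seed 1 --out phantoms
Rscript inst/exec/hyperseg train    --stage 2 --data phantoms/manifest.tsv --epochs 12 --out run
Rscript inst/exec/hyperseg predict  --stage2 run/stage2_best.rds --input phantoms/sample001_vol.nii.gz --out pred.nii.gz --no-crop
Rscript inst/exec/hyperseg evaluate --pred pred.nii.gz --truth phantoms/sample001_lab.nii.gz --out metrics
Rscript inst/exec/hyperseg make-gt  --fat-fraction ff.nii --roi roi.nii --threshold 0.4 --out eat.nii
```

## Limitations

The phantom emulates geometry, contrast and class imbalance, not MRI
physics (no bias fields, Rician noise, or water–fat swaps); a green test
establishes pipeline correctness, not clinical performance. See
`vignettes/hyperbolic-la-eat-segmentation.Rmd` for the model, parameter
and design discussion.
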