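---
title: "Hyperbolic segmentation of the left atrium and its epicardial fat: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hyperbolic segmentation of the left atrium and its epicardial fat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Epicardial adipose tissue (EAT) around the left atrium (LA) is a thin,
fragmented rind of fat sitting directly on the atrial wall. On Dixon
cardiac MRI it is visible as fat-dominant signal (fat fraction above
~0.4 of the normalized map), but it occupies well under 1% of the field
of view, and distinguishing *peri-atrial* fat from fat belonging to
other organs requires spatial context, not just intensity. `hyperseg`
implements a two-stage pipeline:

1. a plain 3D U-Net on the **fat channel** proposes a region of
   interest (its target here is the union of LA and EAT labels — the
   clinical stage-1 target is described only loosely as separating LA
   fat from other fat, so the union is our concrete proxy);
2. the volume is cropped to that region (margin 8 voxels, box grown to
   a multiple of $2^{\mathrm{depth}-1}$ so pooling stays valid), and a
   second network classifies every voxel of the crop into
   {background, LA, EAT} from the water, fat and fat-fraction channels.

The second network is a U-Net whose *encoder* blocks run two branches
off a shared convolution stem $c = \sigma(X \ast W + b)$: the Euclidean
branch keeps $F_e = c$, the hyperbolic branch embeds $c$ into the
Poincaré ball and applies a Möbius convolution,
$F_h = \mathrm{mconv}(\exp_0(c))$. The log-mapped hyperbolic features
are concatenated with $F_e$ and max-pooled. The decoder is Euclidean
(nearest-neighbor upsampling, skip concatenation, convolution); the head
embeds the final feature field into the ball and scores each voxel
against per-class hyperbolic planes (HMLR). The hyperbolic branch gives
voxels a representation in a space whose volume grows exponentially
with radius — the intuition is a better fit for the hierarchical
part/whole structure (heart → atrium → wall → fat rind) than flat
space; the package treats this as the method's hypothesis, not as an
established fact.

### Poincaré-ball operations

The ball of curvature $k > 0$ is $\{p : k\lVert p\rVert^2 < 1\}$ with
conformal factor $\lambda_p = 2/(1-k\lVert p\rVert^2)$. We implement the
standard gyrovector toolkit: Möbius addition

$$q_1 \oplus q_2 = \frac{(1 + 2k\langle q_1,q_2\rangle + k\lVert q_2\rVert^2)\,q_1 + (1 - k\lVert q_1\rVert^2)\,q_2}{1 + 2k\langle q_1,q_2\rangle + k^2\lVert q_1\rVert^2\lVert q_2\rVert^2},$$

Möbius scalar multiplication, the exponential map
$\exp_P(v) = P \oplus \big(\tanh(\sqrt{k}\lambda_P\lVert v\rVert/2)\,
v/(\sqrt{k}\lVert v\rVert)\big)$ and its inverse log map, the signed
distance to a class plane, and the HMLR logit
$\zeta_y \lambda_{p_y}\lVert a_y\rVert/\sqrt{k}\,\cdot\,
\mathrm{asinh}(s)$. The source text we implement from prints several of
these formulas with internal inconsistencies (a squared-curvature
coefficient in the addition, a reciprocal/subtraction form of the
exp/log pair, $p\oplus z$ instead of $(-p)\oplus z$ in the plane
distance); we use the standard forms throughout because only they
satisfy the properties the pipeline itself relies on — the gyrogroup
identities, mutual inversion of $\exp$/$\log$ (features must round-trip
between spaces), and a distance that vanishes at the plane's own offset
point. The test suite asserts exactly these properties.

### Learnable curvature and Riemannian SGD

Curvature is trained through $k = e^{l_k\sigma} + l_0$ with $\sigma$
the trainable scalar (initialized to 0, so $k_0 = 1 + l_0$), $l_k = 1$
a fixed scale, and $l_0 = 10^{-3}$ a strict floor that keeps the ball
from degenerating. Gradients of $k$ are accumulated analytically
through every hyperbolic operation (embedding, Möbius convolutions,
plane distances). Ball-valued parameters — HMLR plane offsets and the
Möbius bias points — are updated by Riemannian SGD: the Euclidean
gradient is rescaled by $4/\lambda_p^2 = (1-k\lVert p\rVert^2)^2$ and
retracted along the exponential map. We normalize with the factor 4 so
that the flat limit $k \to 0$ recovers plain SGD exactly (the
un-normalized $1/\lambda^2$ variant converges to a step of a quarter
size); this is also the convention the op's own flat-limit contract
demands. Momentum is applied to Euclidean parameters only. Manifold
updates stop after `poincare_max_iters` steps (default 10,000),
interpreting the stated iteration cap as a freeze.

## The loss

$$\mathcal{L} = \alpha L_{CE} + \gamma L_{curv} + \delta L_{IDWH} +
\varepsilon L_{W}, \qquad (\alpha,\gamma,\delta,\varepsilon) =
(0.5,\, 0.2,\, 0.5,\, 0.2).$$

* $L_{CE}$: softmax cross-entropy with class weights proportional to
  inverse prevalence *in the batch*, normalized to mean 1 over the
  classes present (absent classes get weight 0). A 9:1 batch therefore
  weights the minority class 9× the majority.
* $L_{IDWH}$: a soft-Dice-form loss with per-voxel weights
  $d_k = 1/(1+d(v))$, where $d(v)$ is the Euclidean distance transform
  (in mm, spacing-aware, exact Felzenszwalb algorithm) to the **LA
  boundary shell** — LA voxels with a 6-neighbor outside the mask
  (volume edges count as outside). Weights are normalized to mean 1,
  so $\delta$ keeps its meaning across volumes; an empty LA mask falls
  back to uniform weights and the loss degrades gracefully to plain
  multi-class soft Dice. Each class term carries a $10^{-6}$ smoothing
  constant so patches with no EAT are well-defined. Alternative laws
  $1/(1+d)^2$ and $e^{-d/\tau}$ are exposed
  (`inverse_distance_weights(law = ...)`) since the exact law of the
  cited weighting is not specified.
* $L_{curv} = (\log k - \log k_{ref})^2$ with $k_{ref}$ the initial
  curvature: the functional form is never given in the source, so we
  chose a log-space quadratic — symmetric under halving/doubling of
  $k$ and dimensionless, preventing both collapse to the floor and
  blow-up.
* $L_W$: mean of squared Euclidean *weight* entries (convolution
  kernels, head weights, plane normals) — biases, ball points, $\zeta$
  and $\sigma$ excluded. Also a choice; L2 is the default reading of a
  "Euclidean weights" term.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `base_channels` | 8 | — | desk-scale width; paper-scale (~tens of M parameters) reachable by config but not needed to learn the phantom task |
| `depth` | 3 | levels | two poolings + bottleneck; receptive field ~20 voxels covers the LA wall + rind at 1.25 mm |
| `patch_size` | 96 | voxels | the reference training patch; tests use 16–24 on small phantoms |
| `epochs` / `batch_size` | 600 / 2 | — | the reference recipe; scaled-down runs use 12–18 epochs |
| `euclid_lr` | 0.01 | — | the source states 0.1 only for the Poincaré layers; the Euclidean rate is unstated, so 0.01 (stable with momentum 0.9) is our default, configurable |
| `euclid_momentum`, `poly_power` | 0.9, 0.9 | — | stated recipe: momentum SGD with polynomial decay $lr_0(1-t/T)^{0.9}$ |
| `poincare_lr` | 0.1 | — | stated rate for manifold parameters |
| `l_k`, `l_0` | 1, $10^{-3}$ | — | curvature scale and floor; $\sigma_0 = 0 \Rightarrow k_0 \approx 1.001$ |
| `eps_ball` | $10^{-5}$ | — | radial clamp margin when projecting into the open ball |
| threshold | 0.4 | fat fraction | strict `>` ("exceeding"); configurable |
| crop margin | 8 | voxels | ≈10 mm of context around the stage-1 mask |

## Numerical choices

* Norms are floored at $10^{-12}$ before division; `atanh` inputs are
  clamped to $1-10^{-7}$; softmax is computed with row-max subtraction;
  Möbius denominators below $10^{-12}$ raise an error rather than
  returning garbage.
* `exp`/`log` at the origin use series-safe small-argument branches
  (`tanh(x)/x → 1`), and their curvature derivatives have the matching
  limits, so gradients are exact at the origin.
* The ball projection active inside `exp0`/Möbius addition is treated
  as the identity in the backward pass (it triggers only at the clamp
  margin); the HMLR head's offsets are projected before use.
* **Float64 saturation at the rim**: with base points at ≥0.99 of the
  ball radius and tangent norms ~2, $\tanh$ arguments reach ~100 and
  the map saturates to the boundary at machine precision — no
  implementation can invert it there. The inversion property is
  therefore tested with base points at ≤0.6 of the ball radius (tangent
  norms up to 2 as stated). Similarly, $k = e^{\sigma} + 10^{-3}$
  rounds to exactly $10^{-3}$ for $\sigma \lesssim -43$ because
  $e^{\sigma}$ falls below the ulp of the floor; the floor test asserts
  $k \ge l_0$ there and strict excess where representable.
* ReLU subgradient at 0 is taken as 0. Gradient-check fixtures jitter
  biases away from zero because a freshly initialized network has many
  pre-activations *exactly* at the kink (zero biases, zero-padded
  inputs), where a central difference and any valid subgradient
  legitimately disagree.
* Argmax ties in prediction break toward the lower class index
  (`ties.method = "first"`), i.e. toward background — the conservative
  choice for a minority-class application.
* Empty masks: Hausdorff/ASSD return `NA` with a warning (undefined,
  not 0); both-empty confusion metrics return 1, one-empty return 0.
* All randomness flows from explicit seeds through R's RNG; single
  -threaded runs are byte-deterministic (asserted down to the written
  `.nii.gz` files).

## The synthetic phantom: what it does and does not establish

The generator emulates the *structure* of the clinical inputs at their
stated geometry (1.25 × 1.25 × 2.5 mm voxels): an ellipsoidal LA blood
pool (water-dominant), a thin wall, a patchy high-fat EAT rind selected
as the top fraction of a smooth random angular field over the
peri-wall shell (default 40% coverage, 3.75 mm thick), distractor fat
blobs ≥ 10 mm from the LA surface labeled background, a smoothly
modulated background, additive Gaussian noise on the water/fat
channels, and a fat-fraction map recomputed from the noisy channels.
Tissue signal pairs (blood (1.0, 0.05), wall (0.8, 0.1), EAT
(0.15, 0.9), distractor (0.1, 0.95), background (0.4, 0.2)) are invented
but constrained so that pre-noise EAT exceeds the 0.4 fat-fraction
threshold and everything else stays below it — making the
semi-automatic ground-truth pipeline verifiable end-to-end (≥95%
recovery at noise σ ≤ 0.05 is a tested criterion). Datasets jitter the
geometry ±20% per sample from a per-sample seed.

It does **not** model MRI physics: no coil bias fields, Rician noise,
partial-volume effects, water–fat swaps, motion, or anatomical
variability beyond ellipsoid jitter. A green end-to-end test
establishes that the implementation is correct and trainable — that
gradients are exact, the losses behave, the pipeline is deterministic,
and the network can learn a geometry-plus-intensity rule — not that the
method reaches any clinical accuracy. The published clinical numbers
are from a private 66-participant cohort and are not reproducible here;
no test asserts them.

One stated expectation did not survive contact with the stated world:
a 30-patch balanced draw was expected to bring LA and EAT voxel tallies
within 3× of each other, but across seeds and patch sizes the measured
ratio is ~2.8–4.2× (the LA is intrinsically ~3× the EAT volume, and
every EAT-centered patch also contains wall). The sampler's tested
guarantees are the ones it actually provides: every patch in bounds,
at least ⌊n/3⌋ patches containing EAT, and the tally ratio bounded (≤5×).

## Open design points and how we resolved them

* **Decoder**: the source mentions hyperbolic refinement "during
  decoding" without architecture; we keep the decoder Euclidean and put
  the hyperbolic computation where it is documented — the dual encoder
  blocks and the HMLR head. This keeps skip connections conventional
  and halves the hyperbolic compute.
* **Möbius convolution approximation**: implemented as the tangent
  -space form `exp₀(conv(log₀(·)))` followed by Möbius addition of a
  learned bias point — the standard memory-saving approximation
  consistent with the stated motivation.
* **Attention**: the "edge weights in the hyperbolic relational space"
  are under-specified; we provide an optional per-voxel gate
  (`use_hyperbolic_attention`, off by default) that scales the
  hyperbolic branch by `sigmoid(−mean squared tangent distance over the
  3³ neighborhood)`, with a full analytic backward pass. It is an
  interpretation, tested for gradient correctness, not a claim about
  the original design.
* **Stage-1 target**: binary LA ∪ EAT (see above). On tiny phantoms the
  fat-only stage-1 plateaus around Dice 0.5 at voxel level but its
  pipeline contract — the margin-expanded crop box covering ~all true
  foreground — is met and is what the test asserts.
* **Fat-fraction normalization**: by the per-volume maximum (the
  pipeline is 3D; the source also mentions per-slice processing), with
  an all-zero guard. Thresholding is strict (`> 0.4`), both
  configurable.
* **Distance example discrepancy**: the 1-D worked example for the
  inverse-distance weights implies an asymmetric distance-to-boundary
  assignment that no symmetric boundary definition reproduces; we
  define $d(v)$ as the unsigned EDT to the LA boundary shell and froze
  test oracles from a brute-force EDT of that definition
  ([1, 0, 1, 2] for mask [0, 1, 0, 0]).

## Limitations

Pure-R + Rcpp training is CPU-bound: a 48³ volume costs ~5 s per
forward+backward pass, so the scaled-down acceptance run trains on 24³
balanced patches (the pipeline's own imbalance strategy) and reaches
mean foreground Dice well above the 0.70 criterion within ~2 minutes.
Paper-scale configurations (96³ patches, 600 epochs, ~40 M parameters)
are expressible through the config but are not practical without an
accelerator. Checkpoints are RDS archives with a version field; they
are runtime artifacts, not shipped data.
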