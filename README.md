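# pestdet

Lightweight single-stage detection of melon-leaf pests, as a modular and
fully desk-testable R toolkit.

Small insects are a hard detection regime: whiteflies and aphids are dense
and tiny (1–3% of the image each), leafminer damage is an elongated tunnel
whose bounding box is mostly background, and moths/beetles sit at another
scale entirely. `pestdet` implements a nano-scale anchor-free detector
(stride-8/16/32 pyramid, decoupled head, distribution-focal box
regression) with four improvements aimed at exactly that regime:

* **EMA attention** (efficient multi-scale attention) at the backbone
  tail: grouped channels, directional 1-D pooling, a 3×3 local branch, and
  cross-spatial attention maps built by matrix products of softmaxed
  global descriptors against the other branch's spatial map.
* **Fusion rewiring**: the bottom-up P4 fusion stage is advanced to P3
  resolution (three-way concat of the P3 head feature, the shallow
  backbone feature and the upsampled top-down feature), so spatial detail
  reaches the heads before it is washed out; a strided pointwise
  convolution projects back to P4.
* **Wise-IoU v3** box loss: `L = γ(β) · exp(d²/D²) · (1 − IoU)` with the
  enclosure diagonal `D²` detached and the non-monotonic gain
  `γ(β) = β / (δ·α^(β−δ))` driven by the outlier degree
  `β = L_IoU / running mean` (α = 1.9, δ = 3, so γ(δ) = 1 and the gain
  peaks at β = 1/ln α). Average-quality anchors get the largest gradients;
  mislabeled/background-heavy boxes are damped.
* **C3k2-B / ARBlock**: the C3k2 inner bottlenecks become adaptive
  residual blocks — separable stem, three dilated separable branches
  (rates 1/3/5), BN + ECA channel attention, pointwise projection and a
  sigmoid-gated blend with the residual stream — cutting ≈0.1 M
  parameters.

Everything is testable without external data: the package ships an
analytic parameter/FLOP profiler for all ablation variants, a seeded
synthetic pest-scene generator, a CPU training workbench (R + C++
reverse-mode tape), greedy NMS and the full metric stack (P/R/F1, AP,
mAP50, mAP50-95, confusion matrices).

## Worked example

```r
library(pestdet)

# profile the fully improved variant (all four flags) at nano scale, 5 classes
p <- profile_variant(variant_flags(ema = TRUE, fusion = TRUE,
                                   wiou = TRUE, c3k2b = TRUE))
p$params_m   # 2.43   (million trainable parameters, 2 dp)
p$gflops     # 6.7    (forward GFLOPs at 640x640, MACs x 2, unfused BN)
p$params     # 2432989 exact scalar count

# the baseline for comparison
profile_variant(variant_flags())$params_m   # 2.52
profile_variant(variant_flags())$gflops     # 6.0

# loss analytics
focusing_gamma(3)                  # 1        (gamma at beta = delta)
focusing_gamma(1)                  # 1.203333 (beta at the running mean)
rwiou(c(0, 0, 10, 1), c(3, 4, 2, 1))  # 1.221403 = exp(0.2)

# train the full variant on seeded synthetic scenes and evaluate on them
scenes <- lapply(1:60, function(i) generate_scene(scene_spec(size = 160),
                                                  seed = 2024 + i))
cfg <- train_config(epochs = 30, imgsz = 160, batch = 8, seed = 1)
run <- train_detector(scenes, variant_flags(TRUE, TRUE, TRUE, TRUE), cfg)
tail(run$log, 1)   # per-epoch box/cls/dfl losses and mean outlier degree
evaluate_detector(run$model, scenes)$map50
```

The profile numbers are exact, deterministic counts from the layer graph
(a test asserts they equal the instantiated model scalar-for-scalar). The
training call is the same 60-scene / 160 px / 30-epoch protocol the
acceptance suite runs; it takes a few minutes on one CPU core, the loss
falls monotonically after smoothing, and the train-split mAP50 ends well
above 0.5 (the suite asserts the bound, not a point value — one run here
printed 0.963 with P 96.7% / R 88.8%).

A command-line front end (`inst/cli/pestdet.R`) wraps the same functions:
`profile`, `generate`, `split`, `train`, `eval`, `predict`.

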