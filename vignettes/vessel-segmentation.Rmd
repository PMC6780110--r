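---
title: "Dual-residual-stream vessel segmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-residual-stream vessel segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Retinal blood vessels are a diagnostic biomarker: diabetic retinopathy
shows up as swelling and neovascularisation (vessel-pixel growth between
visits), hypertensive retinopathy as vessel narrowing (shrinkage). Manual
delineation is slow, and fundus photographs are low-contrast and noisy, so
the practical route is per-pixel semantic segmentation — classify every
pixel as vessel or non-vessel — followed by simple count-based change
detection. `vessnet` implements a compact encoder–decoder network for this
task, together with the data augmentation, class-balanced training recipe,
pixel-wise evaluation metrics, and the screening rule that consumes the
segmentation.

## The network

The architecture is a 16-convolution fully convolutional encoder–decoder
(Vess-Net). Four encoder blocks of two 3×3 convolutions each (with batch
normalization and ReLU) downsample through 2×2 max pooling; four mirrored
decoder blocks upsample through max-*unpooling* that re-places values at
the argmax locations recorded by the paired pooling stage, so spatial
detail survives upsampling exactly — including odd sizes (447 → 223 → 111
→ 55 → 27 and back). Channel widths double per stage
(64, 128, 256, 512 at the default `base_filters = 64`), the deepest
feature map is 27 × 27 × 512 for a 447 × 447 × 3 input, and the final
convolution has one filter per class feeding a per-pixel softmax.

Two residual streams run through the network:

* **Inner projection paths (IRSP-1…6, non-identity).** In every block
  except the first encoder and last decoder block, the block input is
  projected by a 1×1 convolution + BN to the output width, `F`, and added
  elementwise to the second convolution's BN output `S`:
  `Y_i = S(E_i) + F(E_i)` on the encoder side and `Z_j = S'(D_j) + F(D_j)`
  on the decoder side, each followed by ReLU.
* **Outer identity paths (ORSP-1…4).** The activation after the *first*
  ReLU of encoder block *i*, `T(E_i)`, is carried unchanged to decoder
  block *i* and added to the decoder's first activation:
  `T'(D_j) = K(D_j) + T(E_i)`. These provide direct spatial edge
  information and are what lets so shallow a network converge quickly.

That gives 10 residual links in total: 6 projection, 4 identity. The plan
is built declaratively (`plan_vessnet()`), and `describe_plan()` prints
the full per-layer table with parameter counts
(`(k_h·k_w·c_in + 1)·c_out` for a convolution, `2·c_out` for its BN);
the default plan has 9,724,422 trainable parameters.

### Resolved ambiguities

The published layer tables leave a few details open; the package fixes
them as follows and tests the consequences.

* **Padding.** 3×3 convolutions use symmetric single-pixel zero padding at
  stride 1 — the only choice that reproduces the printed shape schedule.
* **ReLU/pool ordering.** The tables annotate pooling as happening before
  the activation. The package places ReLU immediately after each residual
  add and before pool/unpool; since max-pooling commutes with any
  monotone map (`maxpool ∘ relu ≡ relu ∘ maxpool`, asserted numerically in
  the tests), the two readings are numerically identical.
* **Projection input.** The 1×1 projection takes the *block input* —
  post-pool on the encoder side, post-unpool on the decoder side. Decoder
  table rows that list the projection after the add point are treated as
  table layout, not dataflow.
* **Final activation.** The terminal 2-filter convolution keeps its
  BN + ReLU before the softmax, as annotated. With only two classes this
  caps neither class' probability and trains fine in practice.
* **Argmax ties** in prediction go to the non-vessel class — the
  conservative choice for screening, where false vessel growth would flag
  healthy patients.
* **Batch normalization** uses one learned scale and shift per channel
  (the two parameters per channel the tables count; ε = 1e-5 in the
  denominator). Statistics are computed per sample over the spatial field
  rather than per mini-batch: it is deterministic at inference without
  carrying running averages, is well defined for a batch of one, and for
  full-frame inputs the spatial field (~200k pixels) already gives stable
  statistics. This is the one place the package deliberately departs from
  MATLAB-style mini-batch statistics; running statistics are
  implementation-internal either way.
* **Initialisation.** The original network was trained from scratch with
  an unstated scheme; the package uses He-style Gaussian initialisation
  for convolution weights (`sd = sqrt(2/fan_in)`, the standard choice for
  ReLU networks), zero biases, BN scale 1 / shift 0, under a caller-fixed
  seed.

Conv biases are counted as trainable (matching the printed parameter
tables) although the following BN's mean subtraction makes them inert;
their gradient through BN is exactly zero, which the gradient tests
confirm rather than fight.

## Augmentation

Training sets of ~20 fundus images are too small, so the package
implements the deterministic three-stage expansion:

1. **Flips:** originals ∪ horizontal flips ∪ vertical flips (20 → 60).
2. **Recursive translate/crop/resize:** three fixed recipes
   `(dx, dy, flip)` = (10, −10, none), (15, 15, vertical),
   (20, −20, horizontal), each applied to the *accumulated* set and
   appended, doubling per recipe (60·2³ = 480). This accumulate-and-double
   reading is the only one consistent with the published counts.
3. **Non-recursive pass:** three further recipes (−10, 10, none),
   (−15, 15, vertical), (−20, 20, horizontal), each applied once to the
   stage-2 output (3·480 = 1440 new pairs).

The training set is stage 2 ∪ stage 3 = 1920 pairs; the stage-1 set is
not added again. Each recipe flips first, shifts content by `(dx, dy)`
(positive `dx` rightward, positive `dy` downward — the convention is
recorded here because the source is silent), crops the maximal in-bounds
region and resizes back with nearest-neighbour interpolation, applied
identically to image and mask so masks stay binary. Everything is
seed-free and bit-reproducible.

One published inconsistency is flagged rather than resolved: 15 epochs at
3075 iterations implies 205 iterations/epoch, which matches batch-7
drop-last iteration over 1440 images (`floor(1440/7) = 205`), not 1920.
The package drops partial final batches, consistent with that arithmetic,
and leaves the discrepancy alone.

## Training

Cross-entropy is weighted by **median-frequency class balancing**:
`freq_c` is the pixel count of class *c* divided by the total pixels of
the images *containing* *c* (the per-image-containing-class denominator,
the standard reading of the scheme; with two dense classes a global
denominator would differ only when a mask is single-class), and
`w_c = median(freq)/freq_c`. At a ~1:9 vessel:background ratio this
weights vessel errors roughly nine times as heavily as background errors,
which is what keeps sensitivity from collapsing. The loss is the mean
over pixels of `−w_{c(p)} log p_{c(p)}`, with probabilities clipped at
1e-12.

Optimisation is Adam at a constant learning rate of 5e-4, mini-batches of
seven images with per-epoch shuffling, 15 epochs, and a denominator
epsilon of 1e-6 (the published "epsilon" is read as Adam's ε; the
gradient-clipping threshold itself is unstated, so the package clips the
averaged mini-batch gradient by global L2 norm at a configurable
threshold, default 1.0 — nearly inert under Adam's per-parameter scale
normalisation, kept for robustness against rare loss spikes). Images
enter the network raw apart from 0–1 intensity scaling at load time; no
contrast enhancement or channel selection is applied, which is the point
of the architecture.

## Evaluation

Pixel-wise confusion counts give `Se = tp/(tp+fn)`, `Sp = tn/(tn+fp)`,
`Acc = (tp+tn)/(tp+fp+fn+tn)`. Metrics are computed over **all image
pixels by default**, exactly as the formulas are written; because part of
the retinal literature restricts to the circular field of view, every
metric function accepts an optional region mask. AUC is the trapezoidal
area under the ROC swept over all distinct thresholds of the vessel
probability, pooled across the test set by default (a per-image-mean mode
is offered); the test suite cross-checks it against exhaustive
Mann–Whitney pair counting. Whether published fundus metrics were scored
at network resolution or after mapping back to native resolution is
unstated, so `load_pair()` keeps the native mask alongside the resized
one and either can be scored. Error overlays paint tp/fp/fn in
configurable colours (default blue/green/black, following the published
figures; the miss colour is configurable because the figure captions are
not fully consistent) over a dimmed grayscale of the input, with the gray
ramp kept off the pure overlay colours so recounting coloured pixels
reproduces the counts exactly.

## Screening

Between two registered visits, the relative change in vessel-pixel count
`(curr − prev)/prev` is thresholded symmetrically: growth beyond the
threshold flags a diabetic-retinopathy suspect, shrinkage beyond it a
hypertensive-retinopathy suspect. No clinically validated threshold
exists in the source material ("appropriate threshold"); the default 5%
is an explicit placeholder, the single tunable of the rule. Change is
normalised by the previous count over the whole frame; field-of-view
normalisation would only rescale both counts identically for registered
images of the same camera geometry. Image registration is assumed done
upstream.

## Synthetic data

The generator exists so that the full pipeline — augmentation, training,
evaluation, screening — runs and is tested without any dataset download.
It emulates the features that matter for the method: low-contrast
curvilinear branching trees (biased random walks from near the disc
centre, angular jitter sd 0.15 rad, branch probability 0.06, stroke
widths tapering 4 → 1 px), clipped to a circular field of view
(radius 0.95 of the half-side) on a dark reddish textured background with
radial falloff and Gaussian pixel noise (sd 0.04), at a vessel fraction
held inside 5–15% of total pixels — bracketing the ~1:9.2 vessel:background
ratio of real whole-frame masks — by drawing a per-seed target fraction
from the interior of that band and stopping stroke deposition when it is
reached. Everything derives from one integer seed; per-pair seeds are
disjoint offsets of the master seed.

What it does *not* emulate: optic disc and fovea, lesions, vessel
calibre/tortuosity statistics of real vasculature, camera vignetting
beyond a radial ramp, or inter-image illumination variation. Passing the
end-to-end test therefore shows that the implementation can learn
low-contrast curvilinear structure under class imbalance — it says
nothing about clinical-grade accuracy on real fundus data, which requires
the real datasets and full-scale training.

## Problem sizes in the tests

The test suite exercises the full-size (447 × 447, `base_filters = 64`)
network only structurally (plan, shapes, parameter audit). Numerical
forward/backward checks run on 16 × 16 inputs at `base_filters ∈ {2, 4}`
against naive per-pixel reference implementations; the end-to-end
learning check trains the same topology width-scaled to
`base_filters = 16` on 24 synthetic 128 × 128 pairs for the full 15
epochs and scores 8 held-out pairs. For that small-sample regime the
demonstration configuration raises the learning rate to 2e-3 and lowers
the batch size to 4 (≈90 optimisation steps in total; at the full-scale
settings of 5e-4/batch-7 a 24-image run would take only 45 steps, too few
for any configuration to move far from initialisation). These sizes are
the package's chosen demonstration scale: large enough that the network
must genuinely segment, small enough to run routinely on a laptop CPU.

## Known limitations

* Per-sample BN statistics mean batch composition never affects a
  prediction, but also that very small inputs (where a channel is nearly
  constant) lean on the ε floor.
* Training processes images singly and accumulates gradients; there is no
  batched GEMM across images, so full-scale 447 × 447 training is
  CPU-impractical — by design, that regime is out of scope here.
* The screening rule is a count comparison on registered masks; it is not
  a lesion detector and carries no clinical validation.
* GIF ground-truth files (used by one classic dataset distribution) are
  not readable; convert to PNG/TIFF/PNM first.
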