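---
title: "Calibrated convolutional ensembles for musculoskeletal radiographs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrated convolutional ensembles: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(radcal)
```

## The problem and the data model

A musculoskeletal radiograph *study* is one examination of one patient and
one anatomical region, comprising one or more view images that share a
single binary label (0 = normal, 1 = abnormal). The region set `T` defaults
to the seven standard upper-extremity categories (elbow, finger, forearm,
hand, humerus, shoulder, wrist). The package's canonical interchange is a
CSV manifest with one row per image
(`image_id, path, patient_id, study_id, region, label, split`); a
convenience scanner ingests the directory layout of the public MURA
benchmark. Images are 8-bit grayscale PNGs, resized bilinearly to a square
(256 px reference; any smaller side for desk-scale work) and mapped to
`[0, 1]` by the fixed scale `v / 255` — deliberately not per-image min–max,
so constant images stay constant and intensities remain comparable across
images. Already-normalized input (all values at most 1) is only resized,
making preprocessing idempotent.

Training augmentation applies a random sequence of one to three distinct
transformations — horizontal flip, vertical flip, rotation by an angle
uniform in ±30° — sampled without replacement in random order. Rotation
uses inverse-mapped bilinear interpolation and fills exposed corners with
0, matching the black borders of radiographs. The resize interpolation and
the rotation fill are choices of this package (the conventions are not
dictated by the method); both are recorded here rather than inferred.

## Architectures

Three baselines are expressed as declarative specs (`arch_spec`), built
into runnable networks by a small base-R engine (im2col convolutions,
batch normalization with tracked moments, max/average pooling, full
backpropagation, Adam):

* **ConvNet** — a VGG-style stack of 14 3×3 convolutions in width-doubling
  pairs (16…1024), BN + ReLU after every convolution, 2×2 max pooling
  after every pair (so a 256-px input reaches the flatten at
  `256 / 2^7 = 2` px), then FC(512), FC(256) and a single logistic unit.
  The binary output is one sigmoid unit; `p(y=0|x) = 1 − p(y=1|x)`.
* **ResNet** — a stem convolution plus 25 residual blocks in the *full
  pre-activation* ordering (BN → ReLU → conv inside every block).
  Identity-skip blocks preserve shape, so zeroing the residual branch
  makes them exact identities (`M(x) = F(x) + x`), a property the tests
  exercise. Projection-skip blocks (1×1 convolution, stride 2 on the
  shortcut of the pre-activated input) sit at every width change. Only the
  total block count is canonical; the 5-stages-of-5 layout with widths
  16/32/64/128/256 is this package's reference configuration and is
  configurable.
* **DenseNet** — the 169-deep configuration: growth rate 32, bottlenecked
  dense blocks of 6/12/32/32 layers, compressing transitions. Inside a
  block, layer ℓ receives the concatenation of all preceding feature maps,
  so its input width is `c_in + (ℓ−1)·growth`. Depth follows the standard
  weighted-layer naming convention (initial conv + 2 convolutions per
  dense layer + 3 transition convolutions + classifier = 169); there is no
  reading under which the configuration holds 169 *spatial* convolutions.
  The first convolution is re-specified for one grayscale channel rather
  than triplicating the input.

`count_parameters()` gives the closed-form parameter count
(`k²·c_in·c_out + c_out` per convolution, `4c` per BN counting the tracked
moments, `n_in·n_out + n_out` per FC); `n_parameters()` independently
enumerates a built model's tensors, and the two are cross-checked in the
tests. The published grand-total parameter count for the ConvNet cannot be
reconstructed from the published layer table plus any straightforward head,
so the package asserts the derivable convolutional-stack count
(18,876,272) instead. Weight initialization is seeded fan-in-scaled
Gaussian (He); no pretrained weights are assumed anywhere.

## Class-weighted loss and training

With `|N_t|` normal and `|A_t|` abnormal training images of region `t`,
the class weights are `w1 = |N_t|/(|N_t|+|A_t|)` (abnormal) and
`w0 = |A_t|/(|N_t|+|A_t|)` (normal); they sum to 1 exactly, and for the
elbow training counts (1734 abnormal / 2584 normal) give the worked values
2584/4318 and 1734/4318. The loss is the per-instance weighted
cross-entropy summed over instances; during optimization the batch *mean*
is used so the learning rate decouples from batch size (the sum-vs-mean
choice is not dictated by the formula; mean is this package's choice).
Probabilities are clipped to `[1e−7, 1 − 1e−7]` before any logarithm.

Training uses Adam with first/second-moment decay 0.9/0.999 and learning
rate 0.001 (defaults), batch size 32 (16 for the dense model, by
convention), up to 100 epochs. Two stopping-related decisions were open:

* **Early stop** — "convergence of the training loss" is implemented as
  relative improvement `< min_delta` (default 1e−4) for `patience`
  (default 5) consecutive epochs.
* **Checkpoint metric** — "best validation performance" does not name a
  metric; the default is study-level validation ROC-AUC, configurable to
  accuracy. `train_config(restore_best = FALSE)` keeps the final epoch
  instead, which matters when training to saturation on purpose (see CAM
  below): ranking (AUC) typically saturates many epochs before the
  absolute probabilities calibrate around the 0.5 threshold, so the
  best-AUC checkpoint can be an early epoch with near-0.5 outputs.

Every stochastic step derives its seed from the user seed (shuffling from
`(seed, epoch)`, augmentation from `(seed, record)`), so a run is a pure
function of `(seed, config, manifest)` — the tests assert bitwise-equal
histories and weights across repeated runs.

**Fine-tuning.** The calibrated ensemble fine-tunes the designated learner
of each region: weights start from a deep copy of the overall model and
training continues on that region's records only, checkpointing on the
region's validation subset. A zero-epoch fine-tune is an exact copy, and
the provenance field `trained_regions` records the data routing.

## Evaluation and the decision rule

Study probability = arithmetic mean of the view probabilities; decision =
threshold at 0.5, *inclusive* (0.5 maps to abnormal — the boundary side is
a documented choice). Five metrics: ROC-AUC (Mann–Whitney form, ties
half-credited), accuracy, precision (0 with a warning when there are no
positive predictions), recall, and Cohen's κ (`(p_o − p_e)/(1 − p_e)`;
defined as 1 when both vectors are constant and identical). Percent
changes against a baseline model are `100·(P_M − P_base)/P_base`, rounded
half away from zero to integer percent as such tables are printed. Some
published percent figures were evidently computed from unrounded scores
and disagree with recomputation from the printed two-decimal values;
only the self-consistent ones (κ 17 %, precision 8 %, accuracy 6 %, AUC
6 %) are used as acceptance targets. Regions with a single observed class
are reported as `NA`, never dropped.

## Ensembling

`average_predict(p_r, p_d)` implements the traditional two-model ensemble:
probability `(p_r + p_d)/2`, label 1 iff `p_r + p_d ≥ 1` — algebraically
identical to thresholding the mean at 0.5, which the tests verify on 10⁴
random pairs. The third baseline is deliberately not averaged in: the
empirical finding this package follows is that adding it does not improve
the two-model ensemble.

`designate_learners()` implements the 2-of-3 rule: per region, the
candidate strictly best (tolerance 1e−9, so exact ties award no win) in at
least two of validation AUC, accuracy and κ. The published validation
table reproduces the published designation (DenseNet: elbow, forearm;
ResNet: the rest). Ties never occur there, so the fallback — highest AUC,
then first in candidate order — is this package's own, documented rather
than inherited. Designation consumes validation metrics only; routing
(`calibrated_predict()`) sends all views of a study to its region's
fine-tuned learner and records the routed model id.

## Class activation maps

Classic CAM strictly requires a global-average-pooling head; the reference
ConvNet ends in flatten + FC instead. One operation therefore hides two
weighting schemes, with the scheme recorded in the result: when the head
is exactly GAP → single linear unit → sigmoid, channel weights are the
classifier weights; otherwise they are gradient-based (spatial mean of
`∂logit/∂feature-map`, computed before the sigmoid so the weighting is
probability-scale free). In both cases the weighted channel combination is
rectified (evidence *for* the class), bilinearly upsampled to the input
extent, and min–max normalized to `[0, 1]` (a constant map becomes all
zeros). Neither scheme is claimed to be "the" original mapping — the
source description is one sentence — but for GAP heads the two coincide.

A practical observation from the localization experiments: the argmax of
an upsampled CAM lives on the tap's grid, so localization accuracy is
bounded by the final feature-map resolution. With three pooling stages at
48-px input (6×6 tap, 8-px cells) peak-in-box rates hover near chance
plus quantization error even for a saturated model; with two stages
(12×12 tap) the same experiment localizes 70–95 % of lesions. The
acceptance experiment therefore uses the two-stage configuration.

## The synthetic world

The generator emulates the *structure* of the real problem, not its
appearance: multi-view studies (1–4 independent renders of the same
underlying lesion parameters, as if projected at different angles), seven
regions with region-specific signal families and per-region class
imbalance, and exact configured counts (prevalence by construction, not
sampling). Backgrounds are a smooth bone-like ridge (bright band of random
width/curvature) plus correlated low-frequency noise and white pixel noise
(sd 0.05). Three parametric signal families caricature the dominant real
abnormality classes — a dark break across the ridge (fracture), a bright
ellipse (implanted hardware), a high-frequency patch (degenerative
texture) — at amplitude `snr × noise_sd`, with the tight bounding box of
every modified pixel recorded as ground truth.

Defaults state the desk-scale world: 7 regions × (40 abnormal + 60 normal)
train, 20+30 validation, 20+30 test, 64-px images (256 is a parameter
away), default snr 4. A model-free matched filter per family
(difference-of-Gaussians blob contrast; its negation for dark lines;
residual high-frequency energy) reaches AUC > 0.9 at snr 3, certifying
learnability before any network enters the picture. What a green test does
**not** establish: anything about anatomical realism, scanner physics,
label noise, inter-reader variability, or transfer to real radiographs —
the generator shares none of those properties.

For testing evaluation and ensembling without training,
`synth_prediction_table()` draws study scores from a binormal model
(normals `N(−d/2, 1)`, abnormals `N(+d/2, 1)`, probabilities via the
logistic transform), so the analytic AUC is exactly `pnorm(d/√2)` and the
0.5 threshold sits at the class midpoint. The crossed-skill acceptance
experiment states per-region skill directly through this dial — the
cleanest way to realize "model A dominates region 1" without engineering
two architectures whose inductive biases happen to differ by region.

## Numerical choices, in one place

* Probability clipping 1e−7 before logarithms.
* Metric-win tolerance 1e−9 in designation (float noise is a tie).
* Decision threshold inclusive at 0.5 everywhere.
* Δ rounding: half away from zero to integer percent.
* BN: batch statistics in training, tracked moments (momentum 0.9) at
  inference; `4c` parameters counted per BN layer including the moments.
* Rotation fill 0; bilinear resize without aspect preservation.
* Seeds: all derived from the user seed via a multiplicative hash, kept
  below 2³¹.

## Known limitations

* The engine is CPU-bound base R: fine for desk-scale inputs (≤ 64–96 px,
  thousands of images), not for the full 256-px benchmark-scale training
  the reference results would require.
* Probability calibration at the fixed 0.5 threshold converges much more
  slowly than ranking; short desk-scale runs should be read through AUC.
* The MURA tree scanner and the shipped benchmark tables cover the public
  dataset's layout and published statistics; the package does not download
  or redistribute the dataset itself.
* CAM localization accuracy is limited by the final feature-map
  resolution, as quantified above.
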