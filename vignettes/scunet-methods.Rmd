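---
title: "Serial encoder-decoder segmentation with hybrid dilated convolutions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serial encoder-decoder segmentation with hybrid dilated convolutions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scunet)
```

## The model

SCU-Net is a semantic-segmentation network for multi-class brain-tumour
slices (background plus glioma, meningioma and pituitary classes). It chains
two U-Net-style encoder--decoder networks in series: the full-resolution
output of the first decoder is the input of the second encoder, and the two
networks are additionally bridged at every resolution level by channel
concatenation followed by two 3x3 convolutions that restore the layer width.
The intent of the serial design is to extract features twice from the same
scene while sharing per-layer semantics between the two passes, which helps
recover lesion edges that a single encoder--decoder tends to smooth away.

Each encoder has five levels with channel widths (64, 128, 256, 512, 512)
at input resolution 512 x 512, halving the resolution between levels with
2x2 max pooling. In place of plain convolution blocks, every level uses a
*hybrid dilated convolution* (HDC) group: three units of dilated convolution
(kernel 3x3, dilation rates 1, 2, 3), batch normalisation and ReLU. The
dilated convolution computes

$$ (F *_l k)(\mathbf p) = \sum_{\mathbf s + l\,\mathbf t = \mathbf p}
   F(\mathbf s)\, k(\mathbf t), $$

i.e. the kernel samples the input on a grid spread by the rate $l$; rate 1
is ordinary convolution. Varying the rate within a group enlarges the
receptive field without losing coverage.

### The gridding criterion

Stacking dilated convolutions with a shared factor in their rates leaves
periodic holes in the receptive field (the gridding or checkerboard
artifact). The validator implements the standard coverage rule through the
backward recurrence

$$ M_i = \max\big[\, M_{i+1} - 2 r_i,\;
   M_{i+1} - 2 (M_{i+1} - r_i),\; r_i \,\big], \qquad M_n = r_n, $$

where $M_i$ bounds the largest gap between two nonzero positions in the
effective kernel of layers $i..n$. A schedule is accepted when
$M_2 \le K$ (the bottom convolution can cover the residual holes) **and**
the rates share no common divisor greater than 1. For rates (1, 2, 3) with
$K = 3$: $M_3 = 3$, $M_2 = \max[-1, 1, 2] = 2 \le 3$, gcd 1 — valid. The
test suite checks the recurrence against a brute-force oracle that
enumerates the union of sampled offsets of all rate triples up to 6 and
measures the largest hole directly; $M_2$ is an upper bound on that hole in
every case.

```{r}
validate_schedule(hdc_schedule(3, c(1, 2, 3)))
validate_schedule(hdc_schedule(3, c(1, 2, 9)))
```

Two canonical rate sets appear in practice — (1, 2, 3) in the serial
network's encoders and (2, 3, 4) (paddings 2, 3, 4) in the HDC-in-plain-U-Net
ablation; both are available (`hdc_presets()`), with (1, 2, 3) as the
package default.

### Decoders, serial wiring and naming

Each decoder step doubles the resolution with a stride-2 transposed
convolution, concatenates the same-layer encoder feature, and applies two
3x3 convolutions back to the layer width. In the second decoder each level
additionally concatenates the same-layer output of the *first* decoder, so
a level-$l$ feature of decoder 2 sees: the upsampled lower level, the
(recovered) level-$l$ feature of encoder 2, and level-$l$ of decoder 1. The
named activations follow SCU-Net's naming scheme: `feature1..feature5`
(encoder 1), `up4..up1` (decoder 1, `up1` at full resolution), `feature6`,
`feature7'..feature10'` and their recovered `feature7..feature10`
(encoder 2 with cross-links), `up9'..up7'`/`up9..up7` and `up6`
(decoder 2). The classification head is a 1x1 convolution to the class
count followed by a per-pixel softmax. `shape_summary()` computes every
activation shape analytically and the test suite verifies it against real
forward passes over randomised configurations.

Design points the architecture's informal description leaves open, resolved here as package choices:

* **Transposed-convolution kernel.** Descriptions of the decoder variously use 3x3 and
  4x4 upsampling kernels; the package defaults to 4x4 with
  stride 2 because an even kernel at stride 2 doubles resolution with
  uniform overlap (no checkerboard in the upsampling), and 3x3 (with
  asymmetric padding, equivalent to output padding 1) remains available via
  `upconv_kernel = 3`.
* **Layer 5.** The activation naming scheme stops at `feature10'`/`up9'`,
  so level 5 is treated as the bottleneck: there are no distinct
  `up5`/`up10` activations, and the level-5 cross-link concatenates
  `feature5` with `feature10'` before decoding.
* **Serial hand-over.** `up1` (64 channels at full resolution) is the sole
  input of encoder 2; decoder 1 carries no auxiliary segmentation head.
* **Input channels.** The nominal input is a single-channel image converted
  to RGB; the package replicates grayscale input to `in_channels = 3`
  before the first convolution.
* **Recovery convolutions.** The "two 3x3 convolutions" that restore
  channel counts after each concatenation are implemented as
  convolution--batch-norm--ReLU pairs, matching the treatment of every
  other convolution in the network.
* **Initialisation.** He-uniform weights (fan-in), zero biases, batch-norm
  scale 1 / shift 0. Batch-norm statistics are per-channel over the batch
  and spatial axes with momentum 0.1; evaluation uses the running averages.

## The focal Dice loss

Training minimises

$$ L = \omega_1\, \mathrm{FL} + \omega_2\, D^{\gamma} \log(\cosh D), $$

where $\mathrm{FL}$ is the focal loss
$-\alpha (1 - p_t)^{\gamma_f} \log p_t$ averaged over pixels ($p_t$ the
predicted probability of the true class) and $D$ is the soft Dice loss,
$1 - (2\sum p y + \varepsilon)/(\sum p + \sum y + \varepsilon)$ averaged
over the foreground classes ($\varepsilon = 10^{-6}$). The
$\log\cosh$ transform smooths the non-convex Dice loss; the
$D^{\gamma}$ factor adapts the weight of the overlap term to the sample:
poorly segmented samples (large $D$) get a larger multiplier, well
segmented ones a smaller one, so the loss focuses on what is still hard.
The weight ratio defaults to $\omega_1:\omega_2 = 4:1$, the setting used to
train the serial network.

Parameters the loss definition leaves free, fixed here as package defaults and
exposed in `loss_weights()`: $\gamma = 1$ (adaptive exponent),
$\gamma_f = 2$ and uniform $\alpha = 1$ inside the focal term (its standard
values), the $4{:}1$ weights kept unnormalised (rescaling both only rescales
the gradient, which Adam absorbs), and the Dice loss computed per batch
(not per image) before exponentiation. Probabilities are clamped at
$10^{-7}$ before the logarithm.

The closed-form anchors used by the tests: $\log\cosh 1 \approx 0.43378$; a
single pixel with $p_t = 0.5$, $\gamma_f = 2$ contributes
$0.25 \ln 2 \approx 0.17329$; and with $\mathrm{FL} = 0.1$, $D = 0.5$ the
total is $4(0.1) + 0.5 \log(\cosh 0.5) \approx 0.4601$. The analytic
gradient of the full compound loss is verified against central finite
differences through the entire network.

## Evaluation metrics

From the pixel confusion matrix $p_{ij}$ (rows = truth, columns =
prediction, over $k + 1$ classes):

* $\mathrm{MIoU} = \frac{1}{k+1} \sum_i p_{ii} / (\sum_j p_{ij} +
  \sum_j p_{ji} - p_{ii})$
* $\mathrm{MPA} = \frac{1}{k+1} \sum_i p_{ii} / \sum_j p_{ij}$
* mPrecision: mean per-class $TP/(TP+FP)$
* mDice: mean per-class $2TP/(2TP+FP+FN)$
* accuracy: $\mathrm{trace}/\mathrm{total}$.

Conventions: classes absent from both masks are skipped from the per-class
means (their ratios are 0/0); a class absent from the truth alone
contributes 0 where its denominator is defined. Background is included in
the means by default (`include_background = FALSE` switches to
foreground-only averaging). Dataset-level values are means of per-image
metrics, which is permutation-invariant over images.

Boundary metrics operate on 4-neighbourhood class boundaries (the image
border counts as outside). Directed distances are Euclidean on the pixel
grid, computed with an exact two-pass lower-envelope distance transform and
verified against an all-pairs oracle. `hausdorff95()` reports the larger of
the two directed 95th percentiles (the exact maximum via
`percentile = 100`, which is symmetric); `asd()` is the one-directional
mean distance from the segmented boundary to the ground-truth boundary
(a symmetric variant is behind a flag). Pixel spacing defaults to 1.0 and
simply scales the distances; the millimetre figures of clinical reports
correspond to the scanner's pixel spacing, which phantom data does not
have.

## The phantom generator

Real MRI slices with expert labels cannot ship with the package, so all
tests run on synthetic phantoms from `generate_phantom()`: a slightly
elliptical "brain" disk (intensity 0.35 with a smooth random texture) on a
dark background, containing 0--2 filled, rotated elliptical lesions per
image. Each lesion draws its class from `class_probs` and its brightness
from a class-specific distribution (means 0.65 / 0.80 / 0.95 for classes
1--3, s.d. 0.05), so class identity is carried by intensity plus shape —
a deliberate simplification of MRI contrast. Additive Gaussian noise
(s.d. 0.02) is applied and the image clipped to [0, 1]. Lesions are
rasterised by the pixel-centre rule; overlapping lesions resolve by draw
order (later wins); every lesion's exact ellipse parameters are recorded in
the phantom's provenance, which lets tests compare the analytic area
$\pi a b$ against the rasterised pixel count (they agree to within one
perimeter). Masks are encodable as the canonical class colours (red, green,
yellow on black) with an exact round-trip.

What phantoms do **not** model: MRI physics (bias fields, partial-volume
edges, T1/T2 contrast mechanics), anatomical texture, or lesion shapes
beyond ellipses. Passing tests on phantoms therefore demonstrate that the
architecture, loss, optimiser and metrics are implemented correctly and can
learn intensity-plus-shape-coded classes — not that the network reaches any
particular accuracy on clinical data.

The train/test splitter uses the conventional 10:1 reassignment: the test
share is $\lfloor n/11 \rfloor$ with the remainder to training
($n = 110 \to 100/10$), shuffled deterministically by seed. The optional
flip/rotation augmentation stands in for dataset-enlargement
"image enhancement" steps and is off by default.

## Training

`scunet_fit()` optimises the focal Dice loss with Adam
($\beta = (0.9, 0.999)$, $\epsilon = 10^{-8}$) under cosine annealing,

$$ \eta_t = \eta_{\min} + \tfrac12 (\eta_0 - \eta_{\min})
   (1 + \cos(\pi t / T)), $$

evaluated per epoch with $\eta_{\min} = 0$ and no restarts; the recorded
history's learning-rate column equals this closed form exactly. Training length is counted in epochs (default 50), and the default
initial rate $10^{-4}$ suits fine-tuning-scale runs on full-size
images. Epoch order is reshuffled each epoch from the
run seed; everything (initialisation, shuffling, batch assembly) derives
from `control$seed`, so runs are bit-reproducible single-threaded. Batch
size defaults to 4 at 512 x 512
and uses 8 for the 64 x 64 benchmark fixture. A non-finite loss aborts with
the offending batch named.

### The small-scale learning benchmark

The capability check trains a width-reduced network (widths 8, 16, 32, 64,
64) on eight 64 x 64 phantoms (1--2 lesions each) for at most 200
full-batch Adam steps and requires training mDice >= 0.9, passing if at
least 2 of 3 seeds succeed. Because the network trains from scratch (no
pretrained backbone), the benchmark uses an initial rate of $10^{-2}$:
He-initialised batch-normalised networks of this size tolerate —
and at 200-step budgets require — a far larger step size than the
$10^{-4}$ used when fine-tuning a pretrained 512 x 512 model. Training
stops early once the threshold is reached. These problem sizes keep the
benchmark to a few minutes of single-threaded CPU time while still
exercising every layer type of the full architecture.

## Numerical choices

* Convolutions are computed as one BLAS multiplication per kernel offset
  (shift-and-GEMM); dilation only changes the offset stride. Transposed
  convolution is zero-insertion upsampling followed by a padded convolution
  with the spatially flipped kernel, exactly equivalent to the standard
  stride-2 operator.
* Argmax prediction breaks ties toward the lower class index.
* 2x2 max pooling requires even spatial extents; the public entry points
  enforce divisibility by 16 and `predict()` reflection-pads arbitrary
  sizes, cropping the output back.
* Boundary extraction of an absent class raises an error; callers that
  aggregate over classes (e.g. `segmentation_report()`) skip classes with
  no boundary on either side.
* The distance transform is exact (no approximation), so the only
  difference from the all-pairs oracle is floating-point rounding.

## Known limitations

* Single-image 2-D segmentation only; no 3-D convolutions or volumetric
  surface distances.
* No pretrained-backbone loading or freeze/unfreeze schedules; training is
  from-scratch.
* CPU-only; at the full 512 x 512 default width a forward pass is
  seconds-scale but training at that scale is impractical without a GPU
  framework.
* The phantom generator's contrast model is intentionally simple (see
  above); results on it do not transfer to clinical imagery.
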