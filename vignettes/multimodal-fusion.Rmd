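---
title: "Multimodal spectral fusion for plant stress classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal spectral fusion for plant stress classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Plants under different abiotic stresses — heavy metals such as cadmium and
copper, or herbicides such as butachlor and quinclorac — often show no
visible symptoms at moderate doses, yet their optical phenotypes change.
Two imaging techniques capture complementary aspects of those changes:
hyperspectral imaging yields a visible/near-infrared (VIS/NIR) reflectance
spectrum per pixel (here 396 bands over 454–957 nm), which tracks pigment
and structural chemistry, while chlorophyll-fluorescence imaging yields a
fluorescence-induction kinetic curve (here 286 timepoints), which tracks
photosystem-II activity. Measuring both leaves and stems gives four data
sources per plant: `l_visnir`, `s_visnir`, `l_fkc`, `s_fkc`.

`phenofuse` implements an end-to-end deep-fusion approach to five-class
stress classification (control, Cd, Cu, butachlor, quinclorac; labels 0–4)
from these four 1-D curves, together with the preprocessing chain that turns
raw image cubes into per-sample curves, a stratified splitting protocol, an
RBF-SVM reference classifier, and a synthetic data generator used to
benchmark fusion against single-source models.

## The base classifier

Each single source is classified by a shallow gated-attention 1-D CNN
("CNN-S"). The first layer is a multiplicative attention gate

$$Y = \theta_{ReLU}\!\big(W_1\,\theta_{ReLU}(W_2 X + b_1) + b_2\big) \odot X,$$

which rescales each input coordinate by a learned nonnegative gate; a zero
input coordinate therefore always stays zero, and the gate can suppress
uninformative bands. The gate activation is ReLU (not a bounded sigmoid), so
the gate is unbounded above; we follow that form exactly. The hidden width
$h$ of the gate defaults to the input length (square maps), configurable via
`attention_hidden`.

The gated signal passes through three 1-D convolutions (kernel 3, stride 1,
same-length zero padding; 16/32/32 filters by default) with a single
max-pool (size 2, stride 2) after the first convolution, then dense layers
of 512, 128 and 5 units with ReLU activations and a softmax output. Batch
normalization precedes every convolution and dense layer: batch statistics
during training, running averages (momentum 0.9) at inference. The 128-unit
activation before the final layer is the "deep feature" representation used
by feature-level fusion (`penultimate_features()`).

Design points the architecture leaves open, and what we chose:

* **Convolution channel counts** are not dictated by the reference design;
  16/32/32 keeps the network shallow. They are configurable
  (`conv_channels`), and the test suite uses much narrower networks where
  only the mechanics are under test.
* **Padding**: same-length zero padding, so the max-pool is the only length
  reduction and feature bookkeeping is independent of the input length.
* **Pool placement**: directly after the first convolution's activation.
* **Initialization**: fan-in-scaled Gaussian weights with an explicit seed;
  the attention gate starts near the identity (small random maps,
  $b_2 = 1$) so the input signal flows at the first epochs.

## Three fusion levels

For a modality subset (the five named strategies are in
`fusion_strategies()`: both reflectance sources, both kinetic sources, the
leaf pair, the stem pair, or all four):

* **Low-level** (`low_level_model()`): concatenate the raw vectors (up to
  396+396+286+286 = 1364 features) and train one CNN-S on the long vector.
* **Middle-level** (`middle_fusion_model()`): one CNN-S trunk per source,
  truncated at its 128-d deep features; each branch's features pass a
  trainable $128\times128$ linear map with ReLU
  ($\theta_{ReLU}(W_i F_i)$), are concatenated, and feed a dense softmax
  head. One cross-entropy on the fused output trains everything end to end.
  The matrix notation of the fusion rule leaves open whether the branch
  weights are scalars or linear maps; we default to linear maps, matching the matrix-product
  notation, with `scalar_weights = TRUE` as the alternative. Branch maps are
  initialized at the identity so fused features start as the raw deep
  features.
* **High-level / decision fusion** (`high_fusion_model()`): one complete
  CNN-S per source, softmax included; the $5m$ concatenated probabilities
  feed a dense layer with five units and a softmax produces the fused
  decision $y_F$. Training minimizes the joint loss

  $$\mathrm{Loss} = \ell(y, y_F) + \sum_{i=1}^{m} \ell(y, y_i),$$

  the fused cross-entropy plus every submodel's own cross-entropy
  (`joint_loss()`), with probabilities floored at $10^{-12}$ inside the
  logarithm. The sub-losses force each submodel toward the true class
  distribution, so the concatenation is a genuine decision fusion; gradients
  of the fused term also flow through the softmax of each submodel
  (end-to-end, one-stage training). The head consumes probabilities rather
  than logits, because the joint loss treats the submodel outputs as
  probability distributions. The head is initialized as stacked identity
  blocks — exactly the probability-averaging rule of the two-stage baseline
  — so the decision head starts at a sensible fusion rule and end-to-end
  training reweights the submodels from there. With a random head at the
  short training schedules we use, the head's gradients (driven by
  probability-scale inputs) move it too slowly from an arbitrary projection;
  starting at the averaging rule removes that pathology without changing
  the architecture.

Two-stage baselines mirror conventional fusion: `two_stage_middle()` trains
independent CNN-S extractors, freezes them, and trains a fresh CNN-S on the
concatenated 128-d features (five trained models for the four-source
strategy); `two_stage_high()` averages separately obtained probability
vectors and takes the argmax, ties toward the smallest class index.

## Preprocessing chain

From raw cubes to model inputs: `calibrate()` applies black/white reflectance
calibration $(I_{raw}-I_{black})/(I_{white}-I_{black})$; `denoise_curve()`
applies a Daubechies-8 wavelet decomposition at level 3 with soft
thresholding; `roi_mean_curve()` averages the per-pixel curves inside a
leaf or stem mask (denoising each pixel before averaging, as thresholding
and averaging do not commute; an average-then-denoise fast path exists but
is off by default); `truncate_bands()` keeps the closed 454–957 nm window;
`max_normalize()` divides by the maximum.

Choices the reference design leaves open:

* **Thresholding rule**: the universal threshold
  $\sigma\sqrt{2\log n}$ with $\sigma$ the median-absolute-deviation
  estimate from the finest detail level, soft shrinkage. Recorded in
  `wavelet_spec()` so it can be swapped (`"hard"`, `"none"`).
* **Boundary handling**: half-point symmetric extension; the implementation
  reconstructs exactly (machine precision) when thresholding is off, and
  its single-level coefficients were checked against an independent DWT
  implementation.
* **Window inclusion**: closed interval, matching the "454–957 nm" range
  phrasing.
* **Kinetic curves** are only averaged and maximum-normalized; wavelet
  denoising is described for the hyperspectral pixel spectra, and we apply
  it only there by default.

## The synthetic generator

No public dataset accompanies the method, so `generate_dataset()` simulates
the statistical structure the fusion method assumes, with analytically known
class templates (`visnir_template()`, `fkc_template()`):

* Reflectance: a smooth vegetation baseline (low visible reflectance, green
  peak near 552 nm, red absorption dip, sigmoidal red edge to a NIR
  plateau) plus class-specific sums of Gaussian bumps scaled by
  `class_effect_scale`, plus i.i.d. Gaussian noise, clipped at zero.
* Kinetics: a baseline fluorescence $F_0$, a saturating rise toward $F_m$,
  and an exponential relaxation toward a steady state, with the amplitude,
  rise time-constant and steady-state fraction modulated per class.
* Organs differ by a small fixed shift of bump centers and a 0.9 amplitude
  factor, mirroring the strong similarity of leaf and stem curves while
  keeping the four sources non-identical.
* `complementarity` interpolates the class structure: at 0 every class is
  separable in every source; at 1 the herbicide pair (labels 3, 4) shares
  one reflectance template and the heavy-metal pair (labels 1, 2) shares
  one kinetics template, so each single source is structurally blind to one
  pair and capped at 80% accuracy on a balanced set, while all four sources
  jointly separate all classes. This is the regime in which fusion provably
  must beat any single source.
* Default per-class counts (240/360/360/268/358) follow the unbalanced
  group sizes of the rice seedling stress trial the generator emulates; default noise (0.02 in
  reflectance units on 0–1-scale curves) gives within-class variation
  comparable to the class-effect amplitude.

The generator emits already-averaged curves: it does not simulate 2-D
images, pixel-level ROI structure, or biophysical radiative-transfer /
photosystem models, and the 286 timepoints are a uniform index with no
claim about real induction-protocol timing. Passing benchmarks on this data
shows the fusion machinery extracts complementary class signal under known
conditions; it does not certify accuracy on real plants.

## Training protocol

`train()` runs minibatch SGD with the stepped schedule: learning rate
0.005 for the first 100 epochs, one tenth every further 100 epochs
(`lr_at()`), batch size 128, softmax cross-entropy (or the joint loss for
decision fusion). The reference schedule is 500 epochs; `train_config()`
exposes all of it. The optimizer is plain SGD because the stepped schedule
is the one training detail the reference protocol fixes; an adaptive
optimizer would override it. After each epoch the validation set is scored
in inference mode and the returned model is the snapshot with the highest
validation accuracy, ties to the earliest epoch (selection by validation
loss is available via `select_by = "loss"`). The recorded training accuracy
is the running accuracy over the epoch's minibatches (computed from the
training-mode forward passes, so it is free). Epochs are 1-based; the decay
boundaries fall at epochs 101, 201, 301, 401. Partial final batches are
kept; a batch size above the training-set size shrinks with a warning.
Splitting is stratified 4:1:1 per class: validation and test each get
$\lfloor n/6 \rfloor$ samples, training the remainder — with this floor
rule, per-class totals produced under a different rounding convention are
not reproduced exactly, and classes with fewer than three samples go to
training with a warning. Splitting operates at the stress-class level.

Everything is deterministic given the three seeds (generator, split,
training) under single-threaded BLAS.

## Benchmark problem sizes

`fusion_benchmark()` generates data, splits, trains the requested families
and reports accuracies. The package's acceptance checks run it at 60
samples per class with 15 training epochs (batch 32) over three seeds for
the complementary regime, and 30 epochs at one seed for the shared-signal
regime. These sizes are the package's own benchmark conditions: they are
large enough that the structural 80% single-source ceiling and the fusion
gain are well resolved (test sets of 50), and small enough that the whole
benchmark runs on a laptop CPU in minutes. At these scales the expected
picture — every single source well below 0.85 test accuracy at full
complementarity, decision fusion above the best single source, and every
family above 0.95 when all sources share the signal — reproduces the
directional pattern the fusion design is built around — decision fusion
recovering accuracy no single source can reach, and every family learning
when the signal is shared — without claiming performance on real plant
data.

## Known limitations

* The CNN engine is a purpose-built vectorised R implementation over BLAS;
  it is adequate for curve-length inputs and the shallow reference
  architecture, not a general deep-learning framework (no GPU, no
  early stopping, no distributed training).
* The SVM reference classifier wraps libsvm via `e1071`; its full 17×17
  decade grid (289 fits) is expensive on large fused inputs and is not part
  of the synthetic benchmark.
* Momentum/adaptive optimizers are not implemented; the stepped-SGD
  protocol is the contract.
* The ENVI reader covers flat binary cubes (BSQ/BIL/BIP, common dtypes)
  with text headers — enough for the extraction path, not a general-purpose
  remote-sensing I/O layer.
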