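---
title: "Ensemble segmentation with entropy-based confidence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble segmentation with entropy-based confidence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ennseg)
```

## The method

`ennseg` implements binary tumor segmentation of axial CT slices with an
*ensemble of neural networks* (ENN). A single architecture is trained $M$
times (default $M = 10$) on the same tumor-bearing slices; member diversity
comes exclusively from three randomized ingredients, each driven by a
member-specific RNG stream derived from `(base_seed, member_index)`:

1. random weight initialisation,
2. random shuffling of the training slices at every epoch,
3. random augmentations drawn independently at every iteration.

At inference every member sees the identical standardised slice; the $M$
sigmoid outputs $p_m(v) \in [0,1]$ are fused by the elementwise arithmetic
mean

$$\bar p(v) = \frac{1}{M}\sum_{m=1}^{M} p_m(v),$$

and rounded at $0.5$ into the binary mask $y(v) = \mathbf 1[\bar p(v) \ge
0.5]$ (the exact tie $\bar p = 0.5$ maps to foreground; one rule has to be
fixed, and rounding half up is the documented choice). The fused
pre-rounding map is the voxelwise confidence of the ensemble and is what
the visualization module renders.

### Training objective

Members minimise a soft-Dice loss on the sigmoid probabilities,

$$\mathcal L(p, t) = 1 - \frac{2\sum_v p_v t_v + s}
{\sum_v p_v^2 + \sum_v t_v^2 + s},$$

with smoothing constant $s = 1$ by default. On binary predictions the
squared-denominator form coincides with the cardinality form, so
$\mathcal L \to 1 - \mathrm{Dice}$ as $s \to 0$; this identity is enforced
by tests. Dice-based losses behave well under the extreme
foreground/background imbalance typical of tumor slices. Optimisation is
plain SGD with momentum $0.9$, learning rate $0.1$, batches of 64 slices,
20 epochs — the protocol the method was designed with. After every epoch
the validation soft-Dice loss is computed, and the weights of the best
validation epoch are kept; the validation set exists precisely for model
selection and is never used for weight updates.

### Segmentation quality and its dichotomisation

Quality against the reference mask is the Dice overlap
$D = 2|P \cap R| / (|P| + |R|)$. A segmentation is *successful* when
$D > 0.8$, strictly, and *inadequate* when $D \le 0.8$. Degenerate
conventions (needed for totality, never reached on tumor-bearing slices):
both masks empty gives $D = 1$; exactly one empty gives $D = 0$.

Patient-level Dice pools the voxels of all of the patient's tumor-bearing
slices before computing one score, which weights slices by tumor area and
intentionally differs from the mean of per-slice scores when areas differ.

### Confidence: average foreground entropy

The confidence score of a prediction is the mean per-voxel binary Shannon
entropy, **in bits**, of the fused probability over the *predicted*
foreground:

$$E = \frac{1}{|\{v : y_v = 1\}|}\sum_{v : y_v = 1} H(\bar p_v), \qquad
H(p) = -p \log_2 p - (1 - p)\log_2(1 - p).$$

Bits are the right unit here: they give the natural $[0,1]$ range for a
binary decision, with $E = 0$ when all members agree completely inside the
segmentation and $E = 1$ when the fused probability sits at $0.5$
(maximal disagreement). An empty predicted foreground is assigned $E = 1$
and flagged: within this tool every evaluated slice contains reference
tumor, so predicting nothing is a maximal failure and must sort together
with low confidence. The entropy is computed from the fused probability by
default; a variant computed from the fraction of binarized member votes is
available (`foreground_entropy(..., source = "votes")`) since the two
constructions differ in how they weight member calibration.

### Calibration of the entropy cutoff

Confidence is turned into a binary review-flag by thresholding:
`calibrate()` builds the empirical ROC of entropy against success (low
entropy predicts success), computes the AUC as Mann–Whitney concordance
with ties counted $1/2$ (identical to the trapezoidal area), and selects
the operating cutoff $\theta^*$ by the Youden index
$J = \text{sens} + \text{spec} - 1$. Tie rules are fixed and tested:
ties in $J$ break toward higher sensitivity, then toward the lower
cutoff. At assessment time success is predicted iff $E < \theta^*$,
strictly — the tie at the cutoff goes to the review side, which is the
safe side. The numeric cutoff is always a property of a particular model
and dataset: it is recalibrated per run and never hard-coded.
`assess()` deliberately has no access to reference masks; the
calibration/assessment separation mirrors deployment, where no reference
exists.

## The phantom generator

Every downstream stage is testable without clinical data through a
synthetic cohort generator. Each simulated patient draws a shared
geometry — slice count uniform in (5, 20) by default, loosely matching
clinically reported tumor slice counts; a perturbed-ellipse tumor blob
whose in-plane area waxes and wanes over a contiguous run of slices; and
1–3 ellipsoidal organ-like distractors — and renders one volume per
contrast phase. Intensities live in a 12-bit subrange of the 16-bit
scale: background level 1200 plus smooth texture (sd 150, correlation
length `background_texture_scale`), organ offset +350, tumor offset
`tumor_contrast` above local background, additive Gaussian voxel noise
(`noise_sd`, default 60). Phase 2 applies a monotone intensity remap
(gain 0.85, offset +180) of the same noiseless structure with an
independent noise draw — same geometry, same mask — which exercises
patient-grouped splitting exactly where it matters.

Two design choices deserve emphasis:

* **Per-patient enhancement factor.** Each patient's tumor contrast is
  scaled by a uniform draw in $[0.5, 1.3]$. Real cohorts contain both
  conspicuous and poorly-enhancing tumors, and a generator without this
  heterogeneity produces cohorts on which a trained ensemble succeeds on
  essentially every slice, making the success/inadequate dichotomy — the
  entire object of the confidence analysis — degenerate. The range was
  chosen so that a desk-scale ensemble lands in the qualitative regime of
  clinical reports: a clear majority of successful slices with a genuine
  minority of failures.
* **What the phantom does not model.** No anatomy, no Hounsfield
  calibration, no 3D shape statistics, no cystic or infiltrative lesions,
  no scanner effects. Passing tests on phantoms demonstrates that the
  machinery (training dynamics, fusion, entropy, calibration, transfer)
  behaves as specified — not that clinical performance numbers transfer.

Two training-free oracles complete the generator. `degrade_mask()`
produces predictions of controlled badness (erosion, dilation, shift,
partial drop, or a disjoint wrong-region blob whose Dice is 0 by
construction — the archetypal confidently-wrong failure).
`simulate_soft_prediction()` produces probability maps of controllable
quality $q$: the mask is geometrically corrupted (shift up to 4 px,
up to 2 morphological steps), its boundary blurred (Gaussian,
$\sigma = \texttt{blur} + 1.2(1-q)$), and all probabilities compressed
toward $0.5$ as $p \mapsto q\,p + (1-q)/2$. The compression term makes
entropy increase monotonically as quality falls while the geometric term
makes Dice fall, so entropy–quality and Dice–quality monotonicity are
testable properties, and entropy-based success recovery can be validated
with hundreds of samples in seconds.

## The backbone

The architecture is deliberately pluggable behind a registry: the
ensembling, fusion and confidence machinery is backbone-agnostic. The
shipped default, `tiny_unet`, is a compact encoder–decoder sized for
CPU-scale experiments: a 3×3 convolution (1 → C channels, ReLU) at full
resolution, 2×2 mean-pool, a 3×3 convolution at half resolution (ReLU),
nearest-neighbour upsampling, channel concatenation with the
full-resolution features, and a 1×1 convolution to the per-pixel logit
(C = 4 by default, receptive field ≈ 10 px). Convolutions run through
compiled kernels; the backward pass is verified against finite
differences in the test suite. Inputs are standardised per slice (zero
mean, unit variance over the slice) — a rule stored with the model and
applied identically at training and inference. Augmentations default to
horizontal/vertical flips (p = 0.5 each), rotation uniform in ±15°
(bilinear for the image, nearest-neighbour for the mask, zero fill), and
multiplicative intensity jitter in [0.9, 1.1] applied to the image only,
after standardisation so that it changes effective contrast rather than
being cancelled by the normalisation.

## Numerical and protocol choices

* Slice indices are 0-based everywhere in metadata; arrays are accessed
  1-based internally. The NIfTI affine is honoured for spacing only, not
  orientation — the task is per-slice and orientation-agnostic, a
  documented limitation.
* KiTS label semantics (0 background / 1 kidney / 2 tumor) are the
  default with an override (`tumor_label`, `valid_labels`); unknown
  labels are a format error naming the offending label.
* Split sizes use largest-remainder rounding with remainder ties going
  to the later set (validation, then holdout), so 639 patients at
  80/10/10 give 511/64/64. The split shuffles a *sorted* copy of the
  patient list, making membership invariant to input order, and operates
  on patient identifiers so that both contrast phases of a patient can
  never be separated.
* Probability maps are persisted as 32-bit float NIfTI (round-trip error
  below $10^{-6}$); no stage writes wall-clock timestamps, so every
  stage rerun with identical configuration and seed reproduces its
  outputs byte for byte.
* The run configuration carries one global seed that fans out
  deterministically to the phantom, split and ensemble seeds.
* In the reproduction script, confidence is calibrated on the pooled
  non-training evaluations (validation + holdout): a desk-scale holdout
  is only a few dozen slices and can by chance contain no inadequate
  segmentation, in which case the entropy-vs-success ROC is undefined.
  If the pooled set is still single-class, the calibration cohort is
  enlarged with additional simulated patients predicted by the same
  fixed ensemble until both outcomes are observed. Quality summaries
  (median/IQR Dice) remain holdout-only.

## Problem sizes

The test suite and the reproduction script run entirely on synthetic
data at sizes chosen for a single CPU: unit fixtures use 32–48 px
planes and ensembles of 1–2 members; the end-to-end run uses 30
patients × 2 phases at 64×64 with $M = 3$ members trained for the full
20 epochs, and confidence oracles use 200-sample calibration and
transfer cohorts. At these sizes the complete suite finishes in a few
minutes. The full configuration ($M = 10$, 512×512, a deep backbone)
is expressible in the same interfaces but is a GPU-scale undertaking.

## Known limitations

* The shipped backbone is intentionally small; its clinical ceiling is
  far below modern segmentation architectures, and no claim about
  clinical Dice levels follows from phantom results.
* 2D slice independence ignores through-plane context; volumetric
  consistency of predictions is not enforced.
* The entropy score is a *relative* confidence measure: it ranks
  predictions of one ensemble, and its cutoff does not transfer between
  models or datasets without recalibration.
* Confidently wrong segmentations (low entropy, low Dice) exist by
  construction — all members agreeing on the wrong region defeats any
  agreement-based score; the wrong-region oracle exists precisely to
  keep this failure mode visible in evaluation.
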