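---
title: "Universal adversarial perturbations against image classifiers: methods"
author: "uapkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Universal adversarial perturbations against image classifiers: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Deep networks used for diagnostic image classification can be fooled by a
*universal adversarial perturbation* (UAP): a single, image-agnostic
pattern $\rho$, tiny relative to the images themselves, which when added
to *any* input makes the classifier change its answer. `uapkit`
implements the full analysis loop for studying this phenomenon on a
single CPU: synthetic diagnostic-style tasks, a small trainable CNN with
exact input gradients, UAP generation, effect measurement, and the
adversarial-retraining defense.

# The attack model

Let $C(x)$ be the classifier's label for an image $x$ with pixels in the
canonical domain $[0,1]$. A UAP is constrained to an $L_p$ ball,
$\lVert \rho \rVert_p \le \xi$, $p \in \{2, \infty\}$. Rather than fixing
$\xi$ directly, budgets are expressed through the ratio
$\zeta = 100 \cdot \xi / \overline{\lVert x \rVert}_p$ where
$\overline{\lVert x \rVert}_p$ is the dataset's average image norm
(`averageImageNorm()`). Because $\zeta$ is a ratio of like norms it is
invariant to the pixel scale: the same $\zeta$ describes the same
relative perturbation whether pixels are coded in $[0,1]$, as here, or
$0\ldots255$ as in raw 8-bit images (where typical reference values are
hundreds for $L_\infty$ and tens of thousands for $L_2$).

Generation (`generateUAP()`) is the iterative algorithm: start at
$\rho = 0$; for `iMax` passes visit the image set in a fresh seeded
random order (sampling without replacement); for each image not yet
*defeated* — nontargeted: still classified as its clean prediction;
targeted: not yet classified as the target — take one fast-gradient-sign
step at the current adversarial point $\mathrm{clip}(x + \rho)$ and
re-project $\rho$ onto the budget ball. The FGSM step
(`fgsmStep()`) is $+\epsilon\,\mathrm{sign}(\partial L/\partial x)$ at
the true label for nontargeted attacks (ascend the loss) and
$-\epsilon\,\mathrm{sign}(\partial L/\partial x)$ at the target label
for targeted attacks (descend it). The projection (`projectLp()`) is an
elementwise clamp for $p=\infty$ and a radial rescale for $p=2$.

Interpretation choices the algorithm's published description leaves
open, fixed here once:

* **`iMax` counts full passes** over the image set, with per-image
  updates inside each pass; this matches the algorithm lineage the
  attack descends from and keeps `iMax = 15` meaningful for sets of
  hundreds to thousands of images.
* **Updates are gated on not-yet-defeated images** (standard for this
  algorithm family); a pass over a fully defeated set leaves $\rho$
  bitwise unchanged.
* **$\epsilon$ lives in the canonical $[0,1]$ pixel domain** (default
  `0.002`). Published values for this attack were applied in
  framework-internal preprocessed coordinates that cannot be recovered
  from their description; treating $\epsilon$ as a canonical-domain
  knob keeps it in the same coordinate system as $\xi$.
* **Adversarial inputs are clipped** to $[0,1]$ everywhere an image is
  shown to a classifier; $\rho$ itself is constrained only by the ball.
* **Gradients are evaluated at $\mathrm{clip}(x+\rho)$**, not at the
  clean $x$, matching the additive-accumulation reading of the
  algorithm.

Random controls (`sampleRandomUAP()`) are drawn uniformly from the
radius-$\xi$ sphere: for $L_2$, a Gaussian draw rescaled to norm $\xi$
exactly. "Uniform on the sphere" is not well defined for $L_\infty$; the
package uses uniform sign vectors with magnitude $\xi$ (the sphere's
vertices), flagged here as a convention.

# Evaluation

* **Fooling rate** $R_f = |X|^{-1}\sum \mathbb{I}(C(x) \ne C(x+\rho))$:
  the reference is the *clean prediction*, never the true label.
* **Targeted success rate**
  $R_s = |X|^{-1}\sum \mathbb{I}(C(x+\rho) = y)$, with its baseline
  defined as $R_s$ at $\rho = 0$. For a balanced $K$-class set and an
  accurate classifier the baseline is $1/K$ (25% for the 4-class task,
  50% for the 2-class task).
* **Confusion matrices** are row-normalized (rows true, columns
  predicted), so they remain readable for imbalanced tasks.
* **Dominant classes**: nontargeted UAPs tend to collapse predictions
  into a few sinks. The published analyses identify dominant classes by
  inspecting confusion matrices; `dominantClasses()` makes this a rule —
  a class is dominant when its mean column mass over observed rows
  reaches a threshold, default 0.5.
* **Transferability** (`transferabilityMatrix()`): cell $(i,j)$ applies
  model $i$'s UAP to model $j$; the diagonal is the direct attack.

All metrics are pure counting; the tests pin them to naive per-image
loop oracles exactly, with no floating-point tolerance.

# The classifier

No deep-learning framework is assumed. `buildSmallCnn()` is a
self-contained convolutional network — a $2\times2$ average-pooling
stem, two blocks of $3\times3$ convolution + ReLU + $2\times2$ max
pooling, and a fully connected softmax head — with forward, parameter
backprop and *input-pixel* gradients written out in compiled code. The
input gradient is the contract the attack relies on, and is verified
against central finite differences in the tests. Anything else that
answers the `Classifier` contract (scores, labels, input gradients) can
be plugged in via `functionClassifier()` or a subclass, so externally
trained models are usable unchanged.

Training (`trainClassifier()`) is SGD with momentum 0.9, batch 32, a
piecewise-constant learning-rate schedule keyed on the epoch
(`learningRateAt()`; reference schedule `1e-3` through epoch 40, `1e-4`
to 45, `1e-5` after), random rotations in $[-5^\circ, 5^\circ]$ and
random 5% height/width shifts each epoch, and optional oversampling of
minority classes to the majority count for imbalanced tasks. Choices
the recipe's published description does not fix: the loss is
categorical cross-entropy (standard for these architectures);
augmentation border fill is nearest-neighbour; argmax ties break toward
the lowest class index. Labels are 1-based (`1..K`) throughout, the R
convention.

The desk-scale defaults used by the shipped experiments train a
from-scratch network, not a fine-tuned ImageNet backbone, so the
schedule is rescaled for from-scratch training (0.01 for eight epochs,
then 0.003, 10 epochs total); the reference schedule remains the
default of `trainConfig()`.

# The synthetic tasks

`generateDataset()` draws seeded class-conditional images so that every
downstream stage is testable without external data. Three families
carry the class signal:

* **blob** — the default, designed to emulate the geometry of
  diagnostic tasks: class 1 is a lesion-free background (the "normal"
  class most medical datasets have), and each class $k \ge 2$ adds a
  subtle Gaussian bright spot (amplitude 0.12 on a 0.35 background,
  width $\approx 9\%$ of the image side, jittered position) at a
  class-specific location. The low lesion contrast — on the order of
  the pixel noise — keeps decision margins moderate, which is what
  makes a trained classifier both highly accurate *and* genuinely
  attackable at single-digit $\zeta$, as large diagnostic networks are.
  A symmetric, high-contrast design was examined first and produced
  classifiers with margins so wide that no budgeted UAP had any effect;
  the background-class design reproduces the qualitative phenomenology
  of interest (dominant-class collapse under nontargeted attack) and
  reflects how real "normal vs lesion type" tasks are structured.
* **stripe** — sinusoidal gratings with class-specific frequency and
  orientation, random phase.
* **texture** — band-pass filtered white noise with a class-specific
  spatial scale.

RGB tasks additionally tint each class with a distinct color. On top of
the pattern, i.i.d. Gaussian pixel noise of standard deviation
`noiseSd` (default 0.1) is added and the image clipped to $[0,1]$;
`noiseSd` is the difficulty knob. Per-class counts follow proportional
allocation — `round(n * w_k / sum(w))` with the remainder absorbed by
the largest-weight class — which is deterministic and order-independent.

`makeFixture()` packages the three task shapes studied in the reference
setting: a 7-class imbalanced RGB task (train proportions
778/4689/370/229/764/76/94 per 7000), a balanced 4-class grayscale task
(1960/840 per class) and a balanced 2-class grayscale task (900/270 per
class), each scalable. Default images are $64\times64$, not the
$299\times299$ of production pipelines — a runtime choice; the image
size is a config knob and `loadImageFolder()`/`saveImageFolder()` speak
ordinary directory-per-class PNG.

What the generator does *not* emulate: photographic nuisance variation
(illumination, devices, hair, rulers), inter-class feature sharing,
label noise, and the high intrinsic dimensionality of real images.
Passing results on these tasks demonstrate that the pipeline's
machinery is correct and that the qualitative attack/defense phenomena
appear under controlled conditions; they do not quantify the
vulnerability of any real diagnostic model.

# The defense

`adversarialRetrain()` repeats, per round: (1) generate 10 UAPs with
independent seeds against the current model on clean training images;
(2) rebuild the training set with a uniformly random
$\lceil N/2 \rceil$ kept clean and each remaining image perturbed by
one of the 10 UAPs chosen at random (labels stay the true labels,
standard adversarial training); (3) fine-tune for 5 epochs;
(4) generate one fresh UAP against the *just fine-tuned* model;
(5) record that UAP's $R_f$ or $R_s$ on the test split plus clean test
accuracy. Five rounds by default. The fine-tuning rate defaults to the
schedule's smallest value; the shipped experiments use `1e-3`
(one-tenth of their main rate — the analogue of the reference
schedule's final value, which is one-hundredth of its main rate, was
too small to harden the model within five epochs per round at this
scale, and a rate equal to the main rate destabilized it). The random
half-split and UAP assignment are redrawn every round from
round-indexed seeds. `rounds = 0` degrades to a plain evaluation of the
undefended model.

# Problem sizes and numerical choices

The shipped acceptance experiments run on one CPU within minutes, at
these sizes, all stated here as the package's own choices:

* task: 4 classes, $64\times64$ grayscale, 2000 train / 400 test,
  `noiseSd = 0.1`, blob family;
* training: 10 epochs, batch 32 (about half a minute);
* attacks: $\zeta \in \{0, 2, 4, 8\}\%$, $p = 2$, $\epsilon = 0.002$,
  `iMax = 15`, three attack seeds; each UAP is optimized on a seeded
  500-image subset of the training split and always evaluated on the
  full test split;
* defense: 5 rounds, 10 generation UAPs per round (optimized with
  `iMax = 5` on 250-image subsets), 5 fine-tune epochs, evaluation UAPs
  with the full attack configuration on 500-image subsets.

Numerical details: projection uses exact arithmetic
(`xi = zeta/100 * referenceNorm` is checked for identity in the class
validity method); zero gradient components produce zero FGSM components
(`sign(0) = 0`); the $\zeta = 0$ budget yields exactly the zero
perturbation; seeded R-side visit orders are shared between the
compiled fast path and the plain-R reference implementation of
`generateUAP()`, which are tested to agree to $10^{-12}$.

# Known limitations

* Nontargeted UAP effectiveness depends on asymmetric class geometry;
  on perfectly symmetric synthetic tasks per-image gradients cancel and
  the attack (correctly) finds little — a property of the task, not a
  bug in the optimizer.
* The small CNN's robustness differs from that of large pretrained
  backbones in both directions; absolute $R_f/R_s$ values here are not
  comparable to production models.
* `iMax` interpretation (passes) and the $L_\infty$ sphere convention
  are choices where the source description is silent; both are
  configurable points of the implementation rather than claims.
* DeepFool-style inner steps, per-image (non-universal) adversarial
  examples and black-box attacks are out of scope.
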