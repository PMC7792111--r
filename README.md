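# uapkit

Universal adversarial perturbation (UAP) analysis for image
classifiers, in R.

Deep networks used for diagnostic imaging — skin lesion photographs,
retinal OCT scans, chest X-rays — can be fooled by a *single*,
image-agnostic perturbation $\rho$ that is tiny relative to the images
themselves: added to any input it flips the prediction (nontargeted
attack) or steers it into one chosen class (targeted attack). `uapkit`
is a tested, seeded re-implementation of that whole vulnerability
analysis for people who want to study the phenomenon, its metrics and
its defenses end-to-end on a laptop CPU: no GPUs, no downloads, no
pretrained weights.

## What it implements

**Attack.** Iterative UAP generation under an $L_p$ budget
($p \in \{2, \infty\}$): starting from $\rho = 0$, shuffled passes over
the image set add a fast-gradient-sign step
$\pm\epsilon\,\mathrm{sign}(\partial L / \partial x)$ at
$\mathrm{clip}(x + \rho)$ for every not-yet-defeated image, then
re-project onto $\lVert\rho\rVert_p \le \xi$. The budget is expressed
relatively: $\xi = \zeta\% \cdot \overline{\lVert x \rVert}_p$, the
dataset's average image norm. Random controls are sampled uniformly
from the radius-$\xi$ sphere.

**Evaluation.** Fooling rate
$R_f = |X|^{-1}\sum\mathbb{I}(C(x)\ne C(x+\rho))$, targeted success
rate $R_s = |X|^{-1}\sum\mathbb{I}(C(x+\rho)=y)$ with its $\rho = 0$
baseline, row-normalized confusion matrices, dominant-class detection,
and cross-model transferability tables.

**Defense.** Adversarial retraining: per round, 10 fresh UAPs against
the current model; a training set rebuilt half clean / half perturbed;
5 fine-tuning epochs; then a new UAP against the fine-tuned model is
measured on the test split. Five rounds by default.

**Classifier.** A small CNN (conv/pool blocks + softmax head) with
exact input-pixel gradients, written in Rcpp/Armadillo, trained by SGD
with momentum, epoch-keyed learning-rate schedule, rotation/shift
augmentation and optional minority oversampling. Any external model can
be plugged in through the `Classifier` S4 contract
(`functionClassifier()` wraps score/gradient functions).

**Synthetic tasks.** A seeded generator of diagnostic-style image tasks
(lesion-free background class plus subtle class-specific lesions;
stripe and texture families too), including scaled fixtures mirroring
three reference task shapes: 7-class imbalanced RGB, 4-class balanced
grayscale, 2-class balanced grayscale. PNG folder I/O for real data.

## Worked example

```r
library(uapkit)

# a 4-class diagnostic-style task: 64x64, lesion-free class 1
spec <- syntheticTaskSpec(nClasses = 4, imageHeight = 64, imageWidth = 64,
                          patternFamily = "blob", noiseSd = 0.1,
                          nTrain = 2000, nTest = 400, seed = 42)
ds <- generateDataset(spec)

net <- buildSmallCnn(c(64, 64, 1), nClasses = 4, seed = 7)
net <- trainClassifier(net, ds$train,
         trainConfig(epochs = 10,
                     lrSchedule = data.frame(untilEpoch = c(8, Inf),
                                             lr = c(0.01, 0.003)),
                     seed = 11))
accuracy(net, ds$test)
#> [1] 1

# an L2 budget of 8% of the average image norm
budget <- perturbationBudget(p = 2, zeta = 8, dataset = ds$train)
budget
#> PerturbationBudget: p=2 zeta=8% xi=1.88787 (ref norm 23.5983)

uap <- generateUAP(net, ds$train[1:500], budget,
                   attackConfig(epsilon = 0.002, iMax = 15, seed = 1))
foolingRate(net, ds$test, uap)
#> EvaluationReport [test split, 400 images, uap=smallcnn-seed7/nontargeted-seed1]
#>   fooling_rate = 0.4950
#>   dominant classes: 1

rnd <- sampleRandomUAP(c(64, 64, 1), budget = budget, seed = 1)
foolingRate(net, ds$test, rnd)@value
#> [1] 0
```

The perturbation changes 49.5% of test predictions — collapsing them
into class 1, the lesion-free class — while an equally large random
perturbation changes none: the optimization, not the magnitude, is what
bites. A targeted variant
(`attackConfig(mode = "targeted", targetClass = 2)`) steers 85% of
images into class 2 against a 25% baseline, and
`adversarialRetrain(net, ds$train, ds$test, budget, ...)` then cuts that
excess by more than half at unchanged clean accuracy. `runExperiment()`
and `makeFixture()` wire these stages into seeded, manifest-logged
experiment folders.

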