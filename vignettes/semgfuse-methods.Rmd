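---
title: "Methods: virtual-sample augmentation and per-class fusion for sEMG classification"
author: "semgfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virtual-sample augmentation and per-class fusion for sEMG classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semgfuse)
```

## The problem

Surface electromyography (sEMG) gesture recognition suffers from chronic
data scarcity: a recording session yields a handful of repetitions per
gesture per subject, while the feature representations that discriminate
gestures well (time-frequency maps over several channels) are very high
dimensional. `semgfuse` implements a multistage pipeline built around two
ideas for that regime:

1. **Virtual-sample generation** — enlarge the training set by a large
   factor by sampling from per-class, per-feature Gaussians fitted to the
   few real rows, and
2. **per-class classifier fusion** — train several classifier families and
   route each class's decision through whichever classifier recognizes
   that class best.

Between the two sit a spectrogram front end, a multiway (tensor) view of
the features, and a stacked sparse autoencoder that learns a compact code
from the augmented data.

## Pipeline stages

The stage order is fixed: raw signal → spectrogram → standardization →
augmentation → tensor view → autoencoder stack → classifier bank →
per-class fusion. All fitting happens on the training portion of each
cross-validation fold; this is enforced structurally and asserted by the
test suite through a per-stage log of the trial ids every fitting stage
saw.

### Spectrogram representation

Each trial's channels are analyzed with a sliding DFT: a 200 ms window
advanced by 50 ms, a 1024-point transform, one-sided spectra of
`n_fft/2 + 1` bins. At 2000 Hz a 5 s trial yields
`floor((10000 - 400)/100) + 1 = 97` frames of 513 bins per channel. Frames
are indexed from zero and frame `t` covers samples `[tH, tH + W)`
(half-open). Two choices the representation leaves open are fixed here as
defaults and documented rather than buried:

* **Taper**: Hamming, the standard choice for sEMG spectrograms
  (a rectangular taper is available and is what the Parseval identity in
  the tests uses).
* **Scale**: log power with a floor of 1e-12 before the logarithm. The raw
  power of band-limited EMG-like signals spans many orders of magnitude
  across bins; the logarithm keeps the autoencoder's least-squares loss
  from being dominated by a few bins. Power is normalized so the one-sided
  bins of a frame sum to the frame energy divided by the window length.

The per-trial result is both a `feature_tensor` with named axes
(channel × frequency × time) and a flat row in a fixed row-major,
last-axis-fastest order; the two views are exact inverses
(`tensorize_features()` / `flatten_tensor()`), and mode-`n`
unfolding/folding use the same documented ordering so serialized tensors
are portable. The coordinate-transformation machinery
(`coordinate_transform()`, `compose_transforms()`, with Jacobians obeying
the chain rule) is an extension point: the default pipeline transform is
the identity, i.e. tensorization is a pure axis-structured view, which is
the only reading that leaves the full pipeline well defined given only
layer sizes and regularization constants.

### Gaussian virtual-sample generation

For each class `c` and feature `j` the model stores the sample mean
`mu[c, j]` and sample standard deviation `eta[c, j]` (denominator N−1).
Continuous virtual features are drawn independently from
`Normal(mu, eta^2)` (diagonal covariance — no cross-feature covariance is
estimated, deliberately, since with a handful of rows per class a full
covariance would be singular). Discrete features are never transformed:
they receive `eta = 0` and the within-class mode as the single
representative value, the degenerate `N(mu, 0)` draw, so virtual rows can
never introduce a discrete code unseen in that class.

The replication factor `R` multiplies each class's row count: `N_c`
original rows beget `R·N_c` virtual rows, merged with the originals. The
full-scale setting is `R = 1000`; the test profile uses `R = 10`, which
preserves every structural property at a fraction of the cost. Gaussians
are fitted per class, not pooled — labels of virtual rows would otherwise
be undefined. Augmentation is applied to training folds only; the test
fold is never touched.

Standardization (zero mean, unit variance per continuous column, fitted on
the training fold) precedes augmentation. Gaussian fitting is
scale-equivariant, so the order does not change the virtual samples in
distribution, but standardizing first means the autoencoder always sees
unit-scale inputs regardless of `R`.

### Stacked sparse autoencoder

Two greedily trained layers (layer 2 learns to reconstruct layer 1's
codes). Per layer the loss is

```
mean squared reconstruction error
  + lambda * sum(all weights^2)
  + beta * sum_j KL( rho || rho_hat_j )
```

with defaults `lambda = 0.001`, `beta = 4`, `rho = 0.05`, hidden sizes
1200 then 900, and a purely linear encoder transfer. `KL` is the
Bernoulli Kullback–Leibler divergence — the standard sparse-autoencoder
penalty matching the "sparsity regularization / sparsity proportion"
parameterization; it is non-negative and vanishes exactly when every mean
activation equals `rho`. With a linear encoder, activations are not
confined to (0, 1), so the mean activations entering the KL term are
computed on logistic-squashed activations; this keeps the penalty defined
for every transfer while preserving its fixed point.

The optimizer is full-batch gradient descent with a backtracking step
size: any step that would increase the loss is retried at half the step,
and the step grows by 5% after each accepted epoch. The loss trace is
therefore monotone non-increasing by construction, which the tests assert.
Weights initialize Uniform(−r, r) with `r = sqrt(6/(d + h))` from the
layer's derived seed. In the limiting cases the layer behaves as theory
predicts and the tests check: with no penalties, a linear layer with at
least as many hidden units as the data rank drives reconstruction error to
the principal-subspace optimum (zero); with overwhelming weight decay the
weights collapse and the layer degenerates to a constant predictor.

### Classifier bank and per-class fusion

Three families are trained on the encoded features:

* **ELM** (extreme learning machine): random input weights and biases
  Uniform(−1, 1) from a seed, hidden matrix `G = f(XW' + b)`, output
  weights solved by ridge-regularized least squares against one-hot
  targets — or by the Moore–Penrose pseudoinverse when `ridge = 0`, in
  which case `H ≥ N` gives exact interpolation of the training labels.
  Five activations: sine, triangular basis `max(0, 1 − |z|)`, radial basis
  `exp(−z²)`, logistic, and hard limit. The first three are the named
  members of the family; logistic and hard limit complete the
  conventional five.
* **SVM**: one-vs-one soft-margin machines with six kernels — linear,
  quadratic, cubic, and Gaussian at the fine/medium/coarse scales
  `sqrt(d)/4`, `sqrt(d)`, `4·sqrt(d)` (a kernel scale `s` enters the
  radial kernel as `gamma = 1/s²`). Class scores are the
  softmax-normalized sums of signed one-vs-one decision values — a
  deterministic construction that needs no internal probability
  cross-validation.
* **SL** (softmax layer): a multinomial logistic head with weight decay,
  the conventional classification head for stacked autoencoders.

Within each training fold a stratified 25% selection split is held out
(per subject × class stratum). Candidates are trained on the augmented
remainder; the best variant per family is the accuracy argmax on the
selection split (ties to the earliest declared), and per-class accuracies
(recall per class) of the three selected models feed
`select_local_classifiers()`, which assigns each class to the classifier
with the highest recall for it, ties broken by the fixed priority
ELM > SVM > SL. The chosen variants are then retrained on the full
augmented training fold. Selection on a held-out split rather than on
training predictions avoids rewarding interpolation; this is an
interpretation the package makes explicitly.

Fused prediction is per-class score gating: class `c`'s column of the
fused score matrix comes from the classifier that owns `c`, and the
prediction is the argmax, ties to the lowest class index. All score
tables are row-normalized (rows sum to 1), making columns comparable
across classifiers, and when one classifier owns every class the fused
rule reduces exactly to that classifier's own prediction.

### Evaluation protocol

Threefold cross-validation, stratified by repetition within each
(subject, class) group, so with six repetitions each fold tests exactly
two per group against four for training (a 2:1 ratio). Splitting is by
trial — never by analysis window — because windows of one 5 s trial are
heavily correlated and splitting them across folds would leak. Accuracy
is computed per subject and the overall accuracy is the **unweighted**
mean of per-subject accuracies: with subjects at 1.0 (10 trials) and 0.5
(90 trials) the overall is 0.75, not the pooled 0.55.

## The synthetic-EMG generator

No public sEMG corpus backs this package, so the simulator is a
first-class module. It emulates the acquisition protocol: each subject
performs each gesture `n_repetitions` times, 5 s active + 5 s rest per
trial, 2000 Hz sampling, amplifier gain 1000. Active signal per channel is
white noise passed through a second-order Butterworth band-pass centred on
the class's characteristic frequency (defaults spread over the
conventional 20–450 Hz sEMG energy band — the representation is a
modelling convention here, not a measured property), scaled by a
class × channel gain matrix, a log-normal subject gain, and an optional
per-trial force-level factor (labels stay the gesture), plus additive
wideband noise. Rest segments are noise only and are excluded from feature
extraction by default (`include_rest = TRUE` adds rest as an extra class).

What the simulator reproduces: class-dependent spectral structure,
channel gain patterns, subject-level amplitude variation, exact trial
bookkeeping, determinism from a single seed. What it does not: motor-unit
action potentials, electrode geometry, non-stationarity within a
contraction, inter-session drift, crosstalk. Passing tests on this data
therefore demonstrate that the pipeline's machinery is correct and
leak-free and that it preserves recoverable class structure — not that any
particular accuracy will transfer to real recordings.

## Problem sizes and profiles

The `"paper"` profile carries the full-scale constants (R = 1000, hidden
1200/900, 1024-point DFT, 200 ms/50 ms windows, ELM with 500 hidden
units). The `"test"` profile is the package's choice for routine runs and
continuous testing: R = 10, hidden 40/20, a 100 ms window with a 256-point
DFT, 40 autoencoder epochs, ELM with 100 hidden units. The test suite and
the acceptance script use the test profile on a 2-subject, 3-class,
2-channel, 6-repetition simulated study (36 trials) and a 60-row toy
benchmark; a complete threefold run takes on the order of a minute on one
CPU. The shrunken profile changes capacity, not structure: every stage,
selection step and report is identical in form to the full-scale
configuration.

## Numerical choices and degenerate inputs

* Sample standard deviations use denominator N−1; a class with one row is
  rejected with advice (add rows or mark features discrete).
* KL inputs are clamped to `[1e-6, 1 − 1e-6]` with a warning.
* Log-power floors power at 1e-12 before the logarithm.
* Standard deviation zero in standardization becomes scale 1 (constant
  columns pass through centred).
* `ridge = 0` ELM systems are solved by the pseudoinverse; the tests
  verify agreement with an independent SVD-based oracle to 1e-8.
* All ties (variant selection, fusion ownership, fused argmax) break to
  the earliest declared candidate / lowest class index, so reruns are
  bit-identical.
* One master seed fans out to stages through a fixed affine-mod scheme
  (`derive_seed(master, stage, fold)`); every stage seed is recorded in
  the run artifacts so any stage can be re-run in isolation.

## Known limitations

* The diagonal-Gaussian augmentation cannot create inter-feature
  correlation structure beyond what class means encode; strongly
  correlated feature pairs are augmented as if independent.
* The autoencoder's full-batch optimizer is robust but not fast; for the
  full-scale 1200/900 geometry on long feature vectors a full run is an
  offline computation, not an interactive one.
* Fusion selection accuracies come from a single inner split; with very
  few repetitions per stratum these estimates are coarse, and the
  fixed-priority tie-break then effectively prefers the ELM.
* The pipeline evaluates within-subject generalization (the protocol's
  design); leave-one-subject-out transfer is out of scope.

## A worked example

```{r example, eval = FALSE}
library(semgfuse)

spec <- emg_sim_spec(n_subjects = 2, n_classes = 3, n_channels = 2,
                     n_repetitions = 6, seed = 11)
ds <- simulate_emg_dataset(spec)
res <- run_pipeline(ds, pipeline_config("test", seed = 5))
summary(res)
```

The report prints per-subject and per-class accuracies for both splits and
the per-fold fusion assignments. Every number in it is reproducible
bit-for-bit from the config and master seed.
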