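---
title: "Poisson encoding models of limb kinematics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Poisson encoding models of limb kinematics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinencode)
```

## The modeling problem

Neurons in proprioceptive somatosensory cortex modulate their firing with
the state of the limb. An *encoding model* formalizes this as a map from a
vector of kinematic variables $x_m \in \mathbb{R}^K$ at time bin $m$ —
hand position, joint angles, muscle lengths, and/or their first temporal
derivatives — to the expected spike counts $\hat y_m \in \mathbb{R}_{>0}^N$
of $N$ simultaneously recorded neurons in that bin. Comparing models fit on
*extrinsic* inputs (hand coordinates) against *intrinsic* inputs (joint
angles, muscle lengths) asks which coordinate frame the neurons' firing is
most directly related to; comparing signals against their derivatives asks
whether the neurons care about state or about change of state.

`kinencode` implements this comparison pipeline end to end: three model
families, Poisson maximum-likelihood training, deviance-based scoring under
cross-validation, and the four comparative experiments (input classes,
recurrent vs feedforward, data-set size, regularization). Because suitable
primate recordings are not publicly available, the package also ships a
synthetic session generator with a known ground truth, which is what every
test and the acceptance script run against.

## Likelihood, loss, and the pseudo-R²

Counts are modeled as conditionally independent Poisson across bins and
neurons,
$$
P(\{y_{nm}\} \mid \theta)
  = \prod_{n=1}^{N}\prod_{m=1}^{M}
    \frac{\hat y_{nm}^{\,y_{nm}}}{y_{nm}!} e^{-\hat y_{nm}},
$$
and fitting minimizes the normalized negative log-likelihood
$$
L(\theta) = \frac{1}{NM}\sum_{n,m}\bigl(\hat y_{nm} - y_{nm}\log \hat y_{nm}\bigr),
$$
which drops only the $\theta$-independent constant
$\tfrac{1}{NM}\sum \log(y_{nm}!)$ (`poisson_loss()` and a unit test verify
this identity against direct evaluation of the likelihood).

Model quality per neuron is the deviance-based pseudo-R²
$$
pR^2_n = 1 -
\frac{\sum_m \left[ y_{nm}\log y_{nm} - y_{nm} \right] - \sum_m \left[ y_{nm}\log \hat y_{nm} - \hat y_{nm} \right]}
     {\sum_m \left[ y_{nm}\log y_{nm} - y_{nm} \right] - \sum_m \left[ y_{nm}\log \bar y_{n} - \bar y_{n} \right]},
$$
the fraction of the saturated-minus-null log-likelihood gap closed by the
model: 1 is perfect, 0 is no better than a constant mean rate, negative is
worse. The saturated terms use the standard deviance convention
$0\log 0 = 0$. `pseudo_r2()` admits a prediction of exactly zero only where
the observation is zero, so the saturated prediction is always scoreable;
encoder outputs are strictly positive regardless. When the saturated and
null log-likelihoods coincide (a constant-count neuron scored against its
own mean) the measure is undefined and the function returns `NA` with a
warning rather than a misleading number.

A Gaussian variance-accounted-for can be computed from the same tables for
comparison, but all acceptance checks use the Poisson measure.

## Model families

All three families end in an exponential output nonlinearity, guaranteeing
positive rates:

* **GLM** — a linear map from $K$ inputs to $N$ log-rates: Poisson
  regression, the convex baseline. Its log-predictions are exactly affine
  in the features, which the tests exploit.
* **Feedforward network** — two hidden layers of 64 rectified-linear units
  by default.
* **Recurrent network** — three stacked Elman layers of 32 hyperbolic-
  tangent units by default, exponential readout from the top layer. The
  cell type is deliberately the plainest recurrence consistent with
  "3 layers × 32 tanh units": nothing fancier is assumed, though layer
  sizes are overridable.

Pre-exponential activations are clamped to $[-20, 20]$ (about
$2\cdot10^{-9}$ to $5\cdot10^{8}$ expected counts per bin), which prevents
overflow without constraining any physiologically meaningful rate; clamped
units receive zero gradient. Parameters initialize from a fan-in-scaled
uniform $U(-1/\sqrt{f}, 1/\sqrt{f})$ with zero biases; the same seed always
reproduces the same $\theta$ bitwise.

## Training protocol

`training_config()` fixes the optimization protocol: Adam (step $10^{-3}$,
moment decays 0.9/0.999, $\epsilon = 10^{-8}$), batches of 128 data points,
at most 200 epochs. A randomly selected 20% of the training partition is
held out as a validation set; its loss is computed at the end of every
epoch. Under the default early-stopping rule, training halts as soon as the
validation loss *strictly* exceeds its value at the preceding epoch (ties
continue), and the returned parameters are those of the preceding epoch —
reverting costs one parameter snapshot and can only help. Weight decay
(`L1`: $\lambda\|\theta\|_1$; `L2`: $\lambda\sum\theta^2$, the squared-norm
convention of standard weight decay) applies to weights only — biases are
exempt, per the usual convention — and decay-regularized runs train to the
epoch cap with no early stopping, so the two regularizer classes are never
confounded.

Recurrent fits cut the training rows into contiguous subsequences of 50
bins (2.5 s), reset the hidden state at each subsequence start, and form
mini-batches from whole subsequences; trailing remainders shorter than one
subsequence are dropped from training (at most 49 of thousands of bins per
contiguous segment). Prediction runs the full test segment as one sequence
from a zero initial state.

The validation split is re-drawn per cross-validation fold from that
fold's training partition, with the fold's seed; it never touches test
data. Whether the original protocol re-randomized this split per fold is
not knowable from the protocol description; per-fold redrawing was chosen
because it is the only option that keeps every fold self-contained, and the
choice is recorded in each result's metadata.

## Cross-validation design

`cross_validate()` runs k-fold (default 10) evaluation. Two fold
constructions are available:

* `"contiguous"` (default): folds are equal consecutive time blocks.
  Kinematics and spike counts are strongly autocorrelated at 50 ms; block
  folds prevent a model from scoring on bins adjacent to its training data.
* `"shuffled"`: bins are assigned to folds uniformly at random — the
  literal "randomly divided" protocol. Available for comparability;
  recurrent models refuse it since they need contiguous test sequences.

Feature standardization statistics and the reference mean $\bar y_n$ in the
pseudo-R² are computed on the training folds only (mode `"train"`,
default); computing $\bar y_n$ over all $M$ bins is also implemented
(`ybar = "all"`) since the measure's usual definition reads that way, and
the mode is stamped into the result metadata. The training-fold default was
chosen because it is the only leakage-free reading under cross-validation;
on sessions of the sizes used here the two differ negligibly.

Each fold fits from a fresh random initialization derived from the
experiment seed, so fold-to-fold dispersion includes initialization
variability — this is what the reported mean ± sd across folds summarizes.
Experiment functions hold fold assignments and per-fold seeds fixed across
conditions, so the manipulated factor is the only difference (asserted by
tests from the stored config snapshots).

## The synthetic session generator

The generator emulates the statistical structure of a planar random-target
reaching session with simultaneous cortical recordings:

* **Arm**: two links (0.30 m, 0.33 m) with shoulder and elbow joints — the
  smallest geometry in which hand coordinates and joint/muscle coordinates
  are coupled but not interchangeable, which is the property the
  feature-class comparison needs. Six muscles (a mono-articular
  flexor/extensor pair per joint plus a bi-articular pair) with constant
  moment arms of 0.03–0.04 m give muscle lengths linear in joint angles,
  $L_i = \text{rest}_i - \sum_j \text{ma}_{ij}\,\theta_j$, kept strictly
  positive by construction and validated at run time.
* **Behavior**: minimum-jerk point-to-point hand paths
  ($s(\tau) = 10\tau^3 - 15\tau^4 + 6\tau^5$; 0.6 s reaches) to targets
  drawn uniformly in a rectangular workspace inside the reachable annulus,
  each followed by a 0.2 s hold with 1 mm Gaussian positional jitter
  standing in for postural tremor. Joint angles come from the elbow-up
  inverse-kinematics branch (the discrete ambiguity is removed once and for
  all); the round trip through forward kinematics reproduces the commanded
  path to $10^{-9}$. Sampling is 20 Hz, one sample per 50 ms count bin.
* **Spikes**: conditionally independent Poisson counts per bin,
  $y_{nm} \sim \text{Poisson}(\exp(b_n + w_n \cdot g_m))$, where $g$ is a
  z-scored ground-truth feature bank — by default the muscle-length
  derivatives, the feature class that should win the comparison. Per-neuron
  mean rates are drawn from 2–20 spikes/s and baselines $b_n$ are
  calibrated exactly so each neuron's expected rate over the trace hits its
  target. The drive standard deviation defaults to 0.8 log-units, giving
  roughly log-normal rate fluctuation over a ±5× range — strong, clean
  tuning — while keeping expected counts below the 20-per-bin warning cap.
  Alternative ground truths: `hand`, `joint`, `muscle` tuning (for
  ordering-flip controls); `latent`, a shared bank of tanh projections of
  the muscle-derivative signals with per-neuron readouts (for the
  population-benefit experiment); and `disjoint`, one private driver
  channel per neuron (its negative control).

Defaults of `simulate_session()` — 14 neurons, 30 minutes, 20 Hz — mirror
the smallest real recording configuration this class of model is aimed at.

What the generator does **not** emulate: spindle/tendon-organ transfer
functions, muscle activation dynamics, non-Poisson spiking statistics
(refractoriness, bursting, slow rate drift), electrode noise and sorting
errors, behavioral nonstationarity, or 3-D/7-DOF kinematics. Passing tests
on this data therefore demonstrate that the pipeline recovers known
structure of the stated generative form at realistic rates and session
lengths — not that any particular conclusion transfers to cortical
recordings.

## Numerical choices

* Derivatives: central differences on interior samples, one-sided at the
  two edges, computed after (at) the 20 Hz bin alignment. Keeping the edge
  bins (rather than trimming) keeps $M$ identical across feature sets so
  pseudo-R² values are comparable; the edge estimator is exact for linear
  signals and affects 2 of thousands of bins.
* Standardization of inputs is on by default (per training fold) and
  toggleable. The original protocol is silent on input scaling; gradient
  training of layered models without it is fragile enough that "off" is
  only useful as an ablation.
* A kinematics-to-spikes lag option exists (`lag`, default 0 bins) without
  presuming any particular latency.
* `hand` means position only (2 columns); `d_hand` is velocity. The
  extended-extrinsic option (`extended_extrinsic = TRUE`) makes `hand`
  carry position+velocity+acceleration, so both common readings of
  "extrinsic kinematics" are runnable.
* Degenerate inputs: zero-variance feature columns standardize to zero
  with scale 1 and a warning; constant-count neurons make the pseudo-R²
  undefined and return `NA` with a warning; empty sessions ($M = 0$)
  round-trip through the I/O layer as headers only.
* Serialization uses 17 significant digits everywhere, which round-trips
  IEEE doubles exactly: repeated writes are byte-identical and a reloaded
  encoder reproduces predictions bitwise.

## Problem sizes in the tests and acceptance script

The packaged checks run the full pipeline at desk scale, chosen so the
whole suite completes in minutes on one core while every comparison retains
its expected effect direction by a comfortable margin: sessions of 10–25
simulated minutes (12,000–30,000 bins) with 10–14 neurons, 2–3 experiment
seeds, and 3–5 folds. The GLM recovery check uses $M = 20{,}000$,
$K = 4$, $N = 3$ as specified for that property. The comparative
thresholds themselves (orderings by more than one pooled fold-sd,
agreement within two pooled sd, metric exactness at $10^{-10}$) do not
depend on these sizes.

## Known limitations

* The recurrent family implements plain Elman recurrence only as default;
  gated cells are out of scope here, so conclusions about "recurrence"
  mean this cell.
* Weight-decay training always runs to the epoch cap; no learning-rate
  schedules, dropout, or batch normalization are provided.
* No history-filter (lagged basis) feature expansions: the models map
  instantaneous kinematics to instantaneous rate, which is the hypothesis
  class under study.
* The generator's reach-length, speed, and inter-reach statistics are
  plausible for primate reaching but not calibrated to any particular
  animal's behavior; absolute pseudo-R² values on synthetic data should
  not be read as predictions of performance on recordings.
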