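---
title: "Class balancing for small-sample omics data with penalized Wasserstein GANs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Class balancing for small-sample omics data with penalized Wasserstein GANs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

High-throughput omics studies routinely end up with many more samples of one
class than the other — tumours versus adjacent tissue, formula-fed versus
breast-fed infants — and with far more features than samples. Classifiers
trained on such data learn the over-represented class preferentially, and the
usual remedies (SMOTE, random oversampling) interpolate or duplicate existing
minority rows without learning anything about the joint feature distribution.

`ganbalance` implements a generative alternative: a Wasserstein GAN with
gradient penalty, pre-trained on an unlabeled "external" dataset of the same
modality, then re-trained once per class of the small labeled "real" dataset.
The per-class generators are used to synthesize new samples until the classes
are balanced (or both classes are expanded past the majority count), and a
validation protocol quantifies how much a downstream classifier gains.

## The model

The critic $f$ and generator $g$ are fully connected networks. The generator
maps $p$-dimensional standard-normal noise through hidden layers of widths
50, 100, 200 back to $p$ outputs; the critic mirrors it (widths 200, 100, 50)
down to one unbounded score. SELU activations make the stacks self-normalizing
(no batch normalization); weights are Kaiming-normal initialized and
alpha-dropout is used during training. Neither network has an output
activation: data live on an unbounded, transformed scale.

The losses are the gradient-penalized Wasserstein pair, with one addition to
the generator objective:

$$
L_\text{critic} = \overline{f(x_F)} - \overline{f(x_R)}
 + \lambda\,\mathbb{E}_{\hat x}\big[(\lVert \nabla_{\hat x} f(\hat x)\rVert_2 - 1)^2\big],
\qquad
L_\text{gen} = -\overline{f(x_F)} - \alpha \log \lVert X_F \rVert_F ,
$$

where $\hat x = \epsilon x_R + (1-\epsilon) x_F$ with $\epsilon \sim U(0,1)$
per sample, $X_F$ is the generated batch matrix and
$\lVert\cdot\rVert_F$ its Frobenius norm. The $\alpha$ term rewards dispersed
batches: with a handful of training rows the generator otherwise collapses
onto a few modes. $\alpha$ is a per-class hyperparameter (0 or 1 in the
standard protocol; always 0 during pre-training). With $\alpha = 0$ the
generator loss is exactly the classic Wasserstein form.

Two details are deliberate design choices rather than forced by the
formulation, and both sit behind config switches:

* the dispersion term uses the **log** of the norm (`log_norm_penalty`);
  the raw-norm variant is available but couples the gradient scale to the
  batch magnitude;
* the batch norm is the **Frobenius** norm — smooth, cheap, and the default
  matrix 2-norm of the numerical libraries this design descends from.

### Why the gradients are hand-rolled

No deep-learning framework is part of this package's dependency stack, so the
forward passes, backpropagation, and the *double* backpropagation needed for
the parameter gradient of the gradient penalty are implemented directly on
matrices. The penalty gradient uses the standard forward-over-reverse
construction: $\partial P/\partial\theta = v \cdot \partial g/\partial\theta$
with $v \propto (\lVert g\rVert - 1)\, g / \lVert g \rVert$ held fixed, where
$v \cdot g$ is a directional derivative computed by a tangent pass and then
differentiated in reverse. Every gradient path is verified against central
finite differences in the test suite; that check is the load-bearing oracle
for the whole training stack. The penalty is evaluated with dropout disabled
so that the penalized function is deterministic and twice differentiable.

## Training procedure

**Preprocessing.** Each feature is tested against normality with the
D'Agostino skewness test; significant features (p < 0.05) get a Yeo-Johnson
power transform (maximum-likelihood $\lambda$, then standardization), the rest
a robust scaler (median / IQR). One transformer is fitted on 200 random rows
of the external data and drives pre-training; a second is fitted on all real
rows and drives re-training and generation (generated rows are
inverse-transformed with it). The two-component transformer bank (power
transform + robust scaler) follows the declared design; a `nonskew_scaler`
switch restores the standard-scaler reading for non-skewed features.

**Progressive pre-training.** The pair starts with one hidden layer and grows
to three, training to a selected epoch before each growth. Growing preserves
the trained hidden chain of the generator (and the deeper chain of the critic)
bit-exactly; layers whose shapes change are freshly initialized, and the
optimizer state is re-initialized at growth events (new layers need fresh
state). On reaching the third layer the critic:generator ratio drops from 4:1
to 2:1 and dropout rises from 0.5 to 0.7 — a stabilization change kept for all
subsequent re-training.

**Automated training control.** Every training phase is monitored through a
loss trace sampled every `rate_save` epochs, and four pure trace functions
drive all decisions:

* `truncate_trace` removes everything from the first critic loss above 15 or
  below −10 (−15 in re-training) — the offending value included, since it is
  already out of bounds;
* `instability_score` finds the apexes (local extrema, plateaus collapsed,
  endpoints counted as flanking extrema) and averages the top 50 absolute
  differences between consecutive apexes;
* `speed_score` is the mean critic loss of the first 500 epochs minus that of
  the last 500;
* `select_epoch` fits $a e^{-bt} + c$ to the truncated trace by nonlinear
  least squares and returns the sampled epoch at the knee of the fitted curve
  (maximum chord deviation after min-max normalization). A fitted curve whose
  maximum normalized deviation is below 0.02 has no meaningful knee — a
  near-linear trace then falls back to the epoch of minimum critic loss.

Each stage runs two phases: a larger learning rate `lr_1` (the candidate whose
minimum critic loss *above 3* is smallest wins; if no candidate ever exceeds
3, the smallest final loss wins) followed by a smaller `lr_2` (the candidate
minimizing `3 * instability − speed` wins, ties to the smaller rate). The
winning phase-2 run is replayed from its seed up to the knee epoch — replaying
an exact prefix of the same random stream is how early stopping is
materialized without storing checkpoints.

**Re-training.** Two copies of the pre-trained pair are re-trained, one per
class, with batch sizes 10 (under-represented) and 20 (over-represented),
ratio 2:1, dropout 0.7, and per-class $\alpha$. A `classic = TRUE` switch
trains the ablation: fresh full-depth networks, no pre-training, no growing,
$\alpha = 0$.

### Numerical choices

* **Optimizer.** Plain SGD is the declared optimizer, and its momentum slot
  is exposed as `momentum`. The default is classical momentum 0.9: the
  re-training learning-rate grids (1e-5 to 1e-4) move an SGD-trained network
  imperceptibly within any realistic epoch budget, while the literal slot
  value 1 (undamped accumulation) diverges within a few thousand epochs —
  both verified on toy problems in development. 0.9 is the standard value
  for that slot.
* **Divergence guard.** A training run stops recording and returns its
  prefix when any gradient or forward output turns non-finite; the trace
  heuristics then operate on the surviving prefix. The SELU implementation
  propagates rather than traps NaN so a diverged network fails soft.
* **Penalty coefficient.** $\lambda = 10$, the standard value for
  gradient-penalized Wasserstein training; a `use_gradient_penalty = FALSE`
  switch substitutes plain weight clipping for comparison.
* **Determinism.** Every stochastic stage takes a seed; a master seed spawns
  per-stage substreams so adding a method never perturbs another stage's
  randomness. Ties anywhere (learning rates, alpha combinations, feature
  ranks) break deterministically, preferring smaller rates / lower alphas /
  lexicographic names.

## Balancing modes

`target_counts` fixes the arithmetic once for all modes. Balance modes
generate `n_major - n_minor` minority rows. Expanded generation targets
`T = n_major + round(multiplier * n_major)` rows per class (round-half-up;
multipliers 0.25–1.0, where 1.0 doubles the majority class) and generates
`T - n_minor` minority plus `T - n_major` majority rows. Original rows are
always preserved verbatim; generated labels come from the generating GAN's
class, never re-predicted. The baselines are SMOTE (k = 5 nearest-neighbour
interpolation, k auto-reduced for tiny minorities; every synthetic row lies
on a segment between two minority rows) and random oversampling (duplication
with replacement).

## Validation protocol

The classifier is histogram gradient boosting (leaf-wise growth, 31 leaves),
tuned by stratified 5-fold cross-validated AUROC over learning rates
{1e-4, 1e-3, 1e-2, 1, 10} × minimum samples per leaf {1, 10, 25, 50, 75};
ties resolve to the first grid cell. Then 100 iterations (fewer at desk
scale) each regenerate the balanced training set with a fresh seed, refit the
classifier with the tuned parameters, and score AUROC on the held-out
validation split; the report carries the per-iteration scores, their mean and
SD, and `auc_diff = mean − 0.5`. For the GAN methods the protocol is run per
alpha combination (0/0, 1/0, 1/1 for expansion; 0 and 1 for balance — the
0/1 combination is not assessed) and the combination with the greatest mean
AUROC represents the method. Methods are compared with pairwise two-sided
Welch tests on the per-iteration AUROC vectors, Benjamini-Hochberg adjusted
within each experiment (the only per-method samples the protocol produces).
AUROC itself is computed by an established ROC package and cross-checked in
the tests against the normalized Mann-Whitney statistic.

## The simulator

The built-in generator emulates a clustered microarray engine with a fully
specified hierarchical model. For `n_features = 150` features in latent
blocks of `block_size = 10`:

* per-feature baselines on a log-expression scale, $\mu_f \sim N(7, 1)$;
* per-block cluster shifts $\delta_b \sim N(0, s^2)$ applied as
  $\pm\delta_b/2$ to the two clusters, with
  $s$ = `cluster_separation` (default 0.3);
* a shared within-block deviation $z_{ib} \sim N(0, 0.5^2)$ per sample and
  block, which is what makes features within a block correlate;
* independent additive gamma noise with shape 2 and scale 0.5 (mean 1,
  variance 0.5) on every value.

The default separation 0.3 was fixed by a closed-form calculation, not by
experiment: across 15 blocks the expected Mahalanobis separation is
$\sqrt{15 s^2 / (0.25 + 0.05)} \approx 2.1$, putting the optimal linear
classifier near AUROC 0.93. The clusters are therefore imperfectly separable
— the regime where balancing strategy matters. (A separation of 0.8, for
comparison, pushes the ceiling to ~0.997 and every balancing method
saturates.) The external split is a mixture of both clusters at the
simulation's own proportions (default 0.5) with labels stripped; the
validation and external splits are carved deterministically so all
experiment designs share them.

What the simulator does **not** emulate: batch effects, heavy-tailed
per-gene outliers, count-based noise models, or realistic gene-gene
correlation beyond the block structure. Passing tests on this simulator
therefore demonstrate that the machinery works and that the comparative
protocol behaves sensibly, not that the method's real-data advantages
reproduce on arbitrary datasets.

## Stability feature selection

`stability_select` repeats, per iteration: a random 75/25 split; 10-fold
cross-validated tuning of the L1 penalty (LASSO) and of the elastic-net
penalty (mixing parameter 0.5 by default — the mixing value is not dictated
by the protocol and is exposed) on the training part; and recording of the
features with nonzero coefficients. After 10 iterations, features are ranked
by appearance frequency separately per method; the top 25% of each ranking
(ceiling truncation, name-ordered ties) are intersected. The penalty is
re-tuned in every iteration — the protocol optimizes the penalty
systematically, and re-tuning per split is the reading consistent with that.

## Problem sizes used by the tests and the acceptance script

The shipped test-suite and `scripts/acceptance.R` run the full pipeline at
reduced problem sizes, a deliberate package choice so that every behavioural
claim is recomputed from scratch on one CPU. The acceptance script uses
pre-training budgets `max_epochs_1 = 200` and `n_epochs_2 = 1000` per stage
(full three-candidate learning-rate grids; the phase-2 budget is the
standard pre-training value), re-training budgets `max_epochs_1 = 200` and
`n_epochs_2 = 3000` per class (full two-candidate grids; reduced from the
standard 5000), and 30 validation iterations with 60 boosting rounds. The
acceptance tests reuse those budgets for the 120-control design that carries
the expansion-multiplier and method-gap checks, and lighter budgets
(`100`/`1000` epochs, 6 iterations, 40 rounds) for the two flanking designs
of the floor and spread checks. The unit tests use smaller
networks still (hidden widths 6/8/10) for the behavioural contracts —
convergence direction, growth preservation, determinism — while all exact
quantities (losses, penalties, selectors, arithmetic) are tested at full
precision against independent oracles.

## Known limitations

* SGD with momentum, small nets and short budgets leaves the generators
  rougher than a long GPU run would; the knee-point early stopping sometimes
  selects very early epochs when a re-training trace has no decay shape
  (the fallback is the minimum-loss epoch, which is then honest but
  conservative).
* The dispersion coefficient $\alpha$ cannot be tuned from the loss traces;
  in a real deployment it can only be chosen against validation data, which
  biases the estimate — the package mirrors the protocol but the caveat
  stands.
* The simulator's block-correlation model is a simplification; see above.
* SMOTE is implemented with exact nearest neighbours (dense distances),
  adequate for the sample sizes this package targets (tens to hundreds of
  rows), not for large cohorts.
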