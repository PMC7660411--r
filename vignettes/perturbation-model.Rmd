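---
title: "Adversarial perturbation of expression states: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adversarial perturbation of expression states: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its method: the model and its
assumptions, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the numerical and design choices that were
genuinely open.

## The method

Given a min-max-normalized expression matrix (samples × genes, values in
[0, 1]) with class labels, the package trains three dense networks:

1. **Classifier `f`** — dense ReLU layers 1024/512/128 and a linear logit
   head, softmax cross-entropy, Adam at learning rate 0.001, 30 epochs,
   minibatch 32, on a stratified 90/10 split. It plays the role of a
   pretrained tissue/state oracle and is *frozen* afterwards.
2. **Generator `G`** — an hourglass: dense+BN+ReLU encoder 512/256/128,
   three width-128 residual blocks (two dense+BN layers, identity skip
   added before the final ReLU), dense+BN+ReLU decoder 256/512, and a
   gene-dimension tanh output layer without batch norm. `G(x)` is a
   per-gene perturbation in [−1, 1]; the adversarial sample is
   `x_adv = clip(x + G(x), 0, 1)`.
3. **Discriminator `D`** — dense layers 512/256/128 with batch norm and
   leaky ReLU (alpha 0.2) and a single linear output unit, as the
   least-squares GAN objective requires.

Training alternates one discriminator step and one generator step per
minibatch (128 samples, 150 epochs, Adam at 0.0002 for `G` and 0.0001 for
`D`, on a stratified 80/20 split). The discriminator sees real samples
drawn (with replacement) from the *target class only*, paired with an
equal-sized adversarial minibatch: its job is to judge membership in the
target distribution, which is also what the target-anchoring loss assumes.
The generator objective is the weighted sum (all weights 1 by default):

* `L_GAN` — least-squares form with targets real = 1, fake = 0,
  generator target 1: `L_D = mean((D(real)-1)^2)/2 + mean(D(x_adv)^2)/2`,
  `L_G = mean((D(x_adv)-1)^2)/2`.
* `L_adv = max(max_{i≠t} f(x_adv)_i − f(x_adv)_t, κ)` with κ = 0, computed
  on pre-softmax logits (the margin-loss convention of its source; a
  probability-space variant would squash gradients once the attack
  succeeds).
* `L_norm = ‖G(x)‖₂`, mean over the minibatch.
* `L_td = |x_adv − r_t|` with `r_t ~ N(μ_t, Σ_t)` drawn independently per
  sample per minibatch; `μ_t` and the *diagonal* `Σ_t` are fitted on the
  target-class training samples.

### Assumptions

* Expression values are comparable across samples only after the
  normalization chain (log2(v+1) → quantile normalization → per-gene
  min-max); the networks assume inputs in [0, 1].
* Classes are separable by `f`; the perturbation readout is only as
  meaningful as the classifier it attacks. When `f`'s holdout accuracy is
  poor, attack success and gene lists are not interpretable.
* The target class has enough training samples to estimate per-gene means
  and variances (`class_stats()` requires at least 2, usefully dozens).

## Tunable parameters

| parameter | default | units / scale | why |
|---|---|---|---|
| learning rates (G/D/f) | 2e-4 / 1e-4 / 1e-3 | Adam step size | standard recipe for this architecture family |
| epochs (f / GAN) | 30 / 150 | passes over training data | sufficient for convergence at desk scale; no early stopping |
| minibatch (f / GAN) | 32 / 128 | samples | as above |
| holdout fractions | 0.10 / 0.90, 0.20 / 0.80 | per class | single stratified holdout, not resampling |
| κ (`loss_weights`) | 0 | logit margin | attack only needs to cross the boundary |
| term weights | 1 each | — | plain sum of the four loss terms |
| `td_reduction` | `"sum"` | — | see "Loss balance" below |
| k (`significant_genes`) | 2 | standard deviations | two-sided ≈4.6% flag rate under Gaussian perturbations; k = 1 usable for single-gene queries |
| `noise_sd` (simulation) | 0.05 | [0,1] expression scale | separable classes with visible within-class spread |

## Numerical choices

* **Batch norm**: eps 1e-3, running-statistic momentum 0.99, population
  batch variance — the common framework defaults. Running statistics are
  *frozen* (inference mode) whenever perturbations are generated, so
  `apply_generator()` is a pure function of its input; training mode uses
  batch statistics. The generator's output layer carries no batch norm: a
  normalization there would fight the tanh bound.
* **Adam**: β₁ = 0.9, β₂ = 0.999, eps = 1e-8.
* **Initialization**: He-normal for rectifier layers, Glorot-uniform for
  tanh/linear layers; all seeded, so training is bit-reproducible from
  (data, config, seed). Epoch shuffles and target-vector draws are reseeded
  per epoch from the master seed, so stages can be rerun independently.
* **Clipping subgradient**: the gradient of `x_adv = clip(x + P)` is passed
  through where `0 < x + P < 1` and zero outside; `L_norm` acts on the
  pre-clip `P`, so saturated genes still feel the magnitude penalty.
* **Quantile normalization ties** receive the mean of the reference values
  over the ranks the tie group occupies. With ties the "identical sorted
  rows" property is deliberately violated (tied values collapse to one
  value); on continuous data it holds to 1e-9 and the transform is
  idempotent.
* **Constant genes** min-max to 0 rather than being dropped, keeping gene
  indexing aligned with gene sets. `sd = 0` perturbation vectors flag no
  genes (with a warning) rather than erroring.
* **Significance statistics** use the population SD over the gene axis of
  one sample's perturbation vector, with *strict* threshold inequalities;
  ranking ties break lexicographically by gene id so outputs are
  deterministic. Statistics are computed on the raw `P = G(x)` (the
  quantity the model actually outputs), not on the clipped effective
  change `x_adv − x`; the latter is available by passing that difference
  to `significant_genes()` directly.

## Loss balance: why `td_reduction = "sum"`

The L1 target-distribution term is the raw sum over genes, not a per-gene
mean. This matters: the magnitude penalty `‖P‖₂` contributes a per-gene
gradient of about `P_g/‖P‖`, while a gene-averaged L1 term contributes only
`1/n_genes`. At 200 genes the averaged variant is ~40× weaker, and in
practice the generator then stops at the classifier's decision boundary:
planted effects of 0.4 are recovered at ~0.17 and recall collapses. With
the raw sum, each gene's pull toward the target distribution is
scale-matched to the magnitude penalty, and planted effects are recovered
at nearly full strength. The gene-averaged variant remains available
(`loss_weights(td_reduction = "gene_mean")`) for experiments that
deliberately vary gene-set size at fixed weight settings.

## What the synthetic data emulates — and what it does not

`simulate_gem()` draws, per class, a per-gene mean uniform in
[`class_mean_low`, `class_mean_high`] and adds i.i.d. Gaussian noise
(`noise_sd`, clipped to [0, 1]). Independent per-gene class means give
strongly separable classes at moderate noise — the analogue of the dominant
tissue signal in large compendia, which is what makes near-perfect attack
rates attainable. The desk-scale default is 10 classes × 50 samples × 200
genes, noise 0.05.

`simulate_paired_tumor()` plants a tumor/normal contrast: both classes
share a mean vector except on the planted genes, where the tumor mean is
shifted by ±`delta`. Normal-class means for planted genes are drawn away
from the [0, 1] boundary so the planted shift is never clipped away — the
recovery analysis assumes the effect exists at full strength, and a
boundary-clipped "planted" gene would silently weaken the ground truth.
For the patient-style recovery experiment the package uses 150 samples per
class: the paired design emulates cohorts of roughly 150–240 samples per
class, and at much smaller sizes the 80% training split no longer fills
even two GAN minibatches per epoch, which under-trains the generator
rather than testing the analysis.

Deliberately **not** emulated: realistic RNA-seq count distributions
(negative binomial dispersion, library-size effects), gene–gene
correlation, batch effects, or class imbalance. The networks consume
[0, 1]-scaled data, so simulation happens on that scale directly. Passing
tests on this generator therefore demonstrates that the machinery —
training, attack, thresholding, direction labelling — is correct, not that
the method's biological findings transfer to any particular real cohort.

## Direction naming

Perturbations aimed at a *normal* target invert the usual reading: a
positive perturbation raises a gene toward normal, so the gene is *lower*
in the tumor (tumor-downregulated), and vice versa. Because this reversal
is easy to get wrong, the mapping is centralized in the `semantics`
argument of `significant_genes()` / `genes_by_direction()`, and every
output carries both the raw sign and the tumor-relative label.

## Problem sizes

The experiments the package's checks run at: the 10-class attack
replication (500 samples × 200 genes; classifier 30 epochs, GAN 150
epochs) and the paired recovery experiment (300 samples × 200 genes), each
a few minutes of CPU time; unit tests use miniature versions of the same
designs. These sizes were chosen so the whole suite is comfortably
runnable on a laptop while keeping every training schedule (epochs,
batches, learning rates) at its standard value.

## Known limitations

* Min-max scaling is fitted on the full assembled matrix by default, so
  patient/test samples appended later should be appended *before*
  normalization (`normalize_gem()` on the combined matrix); `minmax_apply()`
  projects later samples onto a fitted scaler (with clipping) when joint
  refitting is not possible. Quantile normalization is likewise refit
  jointly by default — projecting a new sample onto a frozen reference
  distribution is possible (`quantile_normalize` on the combined matrix vs
  mapping through the stored reference) but joint refitting is the default
  because the scaler and reference are cheap to recompute.
* `Σ_t` is diagonal. With genes ≫ samples a full covariance is singular;
  diagonal sampling is well defined at any dimension, at the cost of
  ignoring gene–gene correlation in the target anchors. A full-covariance
  draw could be added via eigendecomposition with a variance floor, but the
  diagonal form is the supported path.
* `r_t` draws are not clipped to [0, 1]: the loss uses the Gaussian draw as
  written, and with class variances on the [0, 1] scale the mass outside
  the cube is negligible for real data.
* One discriminator update per generator update, no update-ratio
  scheduling, no early stopping, no adversarial-robustness defenses for
  `f` — the attack is *supposed* to succeed; a hardened classifier would
  measure something else.
* The engine is plain R on BLAS. It is entirely adequate at desk scale
  (hundreds of samples, hundreds to thousands of genes); at compendium
  scale (tens of thousands of genes, 150 epochs) a GPU framework would be
  the right tool, and the architecture is standard enough to port directly.
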