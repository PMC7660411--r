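# gempert

Adversarial perturbation of gene expression states, for "n = 1"
differential-expression analysis.

## The problem

Cohort differential-expression methods (DESeq2, edgeR, limma) need replicated
groups. A patient walks in with one tumor RNA-seq sample — n = 1 — and no
statistics can be computed from that sample alone. `gempert` attacks this by
learning, from a reference cohort, the *perturbation* that moves any
expression profile from a source state (for example a tumor subtype) into a
target state (for example healthy tissue). Applied to one patient sample,
the learned per-gene perturbation vector is a readout of which genes must
change, and in which direction, to make that particular tumor look normal —
a single-sample surrogate for a differential-expression contrast.

## The model

Three dense networks are trained on a min-max-normalized expression matrix
(samples × genes, values in [0, 1]):

* a **classifier** *f* (1024/512/128 ReLU layers) assigning tissue/state
  labels, trained first and then frozen;
* a **generator** *G* (hourglass 512/256/128, three width-128 residual
  blocks, 256/512 decoder, tanh output) producing a perturbation
  *P* = *G*(x) ∈ [−1, 1] per gene, so the adversarial sample is
  x_adv = clip(x + *G*(x), 0, 1);
* a **discriminator** *D* (512/256/128, batch norm + leaky ReLU) judging
  whether a sample comes from the real target class.

The generator minimizes the sum of four terms:

* L_GAN — least-squares GAN loss against *D*;
* L_adv = max(max_{i≠t} f(x_adv)_i − f(x_adv)_t, κ) — a margin loss (κ = 0)
  that is zero once *f* assigns the target class *t*;
* L_norm = ‖G(x)‖₂ — keeps perturbations small;
* L_td = |x_adv − r_t|, r_t ∼ N(μ_t, Σ_t) — an L1 anchor pulling the
  adversarial sample into the target class distribution (diagonal Σ_t
  fitted on training samples).

A perturbed sample is *valid* if *f* classifies it as the target class; the
fraction of valid held-out samples is the **attack success rate**. For a
single sample perturbed tumor→normal, genes whose perturbation lies outside
mean ± 2·sd of that sample's perturbation vector are reported as
significant: positive = tumor-downregulated, negative = tumor-upregulated.

## Worked example

```r
library(gempert)

# a synthetic 10-class cohort standing in for a multi-tissue compendium
g   <- simulate_gem(simulation_spec(n_classes = 10, n_genes = 200,
                                    samples_per_class = 50, seed = 42))
cfg <- training_config(seed = 42)           # 30/150 epochs, lrs 1e-3/2e-4/1e-4
f   <- train_target_model(g, cfg)
f
#> <gempert_target> 10 classes, 200 genes; holdout accuracy 100.0% (n = 50)

gen <- train_generator(g, f, cfg, target_class = "class_0")
rec <- perturb_gem(gen, f, subset_samples(g, gen$holdout_ids))
attack_success_rate(rec)
#> [1] 100
```

The classifier separates the 10 simulated classes perfectly, and the trained
generator moves every one of the 100 held-out samples (from all classes)
across the decision boundary into `class_0` — an attack success rate of
100%. Per-sample gene lists then come from the perturbation vectors:

```r
sg <- significant_genes(rec[1, ], k = 2, semantics = "tumor_to_normal")
sg
#> <significance_result> sample_0044: 200 genes, mean -0.002745, sd 0.04563, k = 2
#>   positive (tumor-downregulated): 5 genes
#>   negative (tumor-upregulated): 1 genes
tidy(sg)       # per-gene tibble; autoplot(sg) shows the thresholded histogram
```

The 2-sd threshold adapts to each sample's own perturbation spread, so only
the most extreme genes of this sample are flagged. All numbers above were
produced by the code shown (fixed seeds; training is deterministic given
the seed).

Real data enter through `read_gem()` (tab-delimited FPKM-like matrices,
genes as rows), `read_labels()`, `read_gmt()` (MSigDB gene sets) and the
normalization chain `normalize_gem()` = log2(v+1) → quantile normalization →
gene-set subsetting → per-gene min-max to [0, 1]. External DESeq2-style
result tables are consumed by `read_dge_table()` + `dge_overlap()`;
between-patient gene-list agreement comes from `pairwise_overlap_matrix()`.

A command-line wrapper for the five workflow steps
(simulate / train-target / train-gan / perturb / analyze) is installed at
`inst/scripts/gempert`.

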