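# flowsynth

Normalizing-flow generative models for single-cell RNA-seq expression data,
with class-balanced synthetic cell generation and a full fidelity/benchmark
evaluation suite — for computational biologists who need to augment
under-represented cell types before training cell-type classifiers, and for
anyone evaluating how faithfully synthetic expression profiles match real
ones.

## What it implements

**Models.** Two exact-likelihood flows over log-normalized cells × genes
matrices:

* **MAF flow** (`build_maffb()`): a masked affine autoregressive flow. Each
  feature is transformed as `z_i = (x_i − μ_i(x_<i)) / σ_i(x_<i))`, with the
  conditioner a masked (MADE-style) ReLU network, triangular Jacobian, and
  log-determinant `−Σ_i log σ_i`.
* **Mixture-of-experts attention flow** (`build_moefb()`): a learnable
  contextual feature mask (`x' = x⊙(1−m) + x̄·m`, `m = 0.5·sigmoid(·)`)
  in front of blocks of `[ActNorm, MoE attention coupling, ActNorm, MAF]`.
  The coupling splits features with an alternating binary mask, runs the
  pass-through half through 4 multi-head attention experts (10 heads each)
  mixed by a softmax gate, and applies `z_b = x_b ⊙ e^s + t` with
  `s = tanh(·)`, so `log|det J| = Σ_{j∈b} s_j`.

Both train by minibatch maximum likelihood under the change-of-variables
rule, `log p(x) = log N(z; 0, I) + Σ log|det J|`, with fully analytic
gradients written in R and verified against finite differences.

**Protocols.** Q3 class balancing (per-type flows raise every cell type to
the third quartile of class sizes), label-free matched-size generation,
proportional subsampling, QC/normalization/HVG preprocessing, a seeded
negative-binomial simulator of imbalanced scRNA-seq data, and a stratified
k-fold benchmark that compares a random-forest cell-type classifier trained
on original vs balanced data and scores fidelity (per-feature Wasserstein
distance, correlation discrepancy, multi-scale RBF MMD) in PC-50 space.

## Worked example

Simulate an imbalanced dataset (four cell types, 20:1 ratio), preprocess,
balance it with per-type MAF flows, and measure fidelity:

```r
library(flowsynth)

ds <- simulate_fixture(fixture_config(seed = 7))   # 2000 cells x 200 genes
ds <- preprocess_pipeline(ds, min_class = 10, min_cells = 20,
                          min_genes = 20, n_hvg = 150)

plan <- q3_plan(ds$labels)
plan
#> # A tibble: 4 × 3
#>   cell_type observed target
#> 1 type_1        1233      0
#> 2 type_2         507    182
#> 3 type_3         194    495
#> 4 type_4          66    623
attr(plan, "q3")
#> [1] 689

cfg <- train_config(model = "maf", hidden_features = 32,
                    learning_rate = 0.02, n_iterations = 30, seed = 1)
models <- fit_per_type(ds, cfg, plan)
synth <- generate_balanced(models, plan, seed = 2, genes = ds$matrix$genes)
synth
#> <labeled_dataset> 1300 cells x 150 genes [lognorm], 3 cell types

pc <- pc50_project(ds$matrix$values, list(synth$matrix$values))
evaluate_fidelity(pc$reference, pc$queries[[1]], representation = "pc50")
#> # A tibble: 3 × 6
#>   metric   value n_real n_synth representation scales
#> 1 wd     0.253     2000    1300 pc50           0.005,0.01,0.1,0.5,1,2
#> 2 cd     0.0543    2000    1300 pc50           0.005,0.01,0.1,0.5,1,2
#> 3 mmd    0.00128   2000    1300 pc50           0.005,0.01,0.1,0.5,1,2
```

The plan raises every class to `max(observed, Q3) = 689` cells: the three
minority types receive 182 + 495 + 623 = 1300 synthetic cells. The low
discrepancies (WD 0.25, CD 0.054, MMD 0.0013 in PC-50) say the synthetic
pool sits close to the real distribution. `run_benchmark()` wraps the same
steps in stratified cross-validation and adds the original-vs-pooled random
forest comparison; `tidy()` and `autoplot()` work on its result, on fitted
flows and on metric reports.

A command-line front end covering `simulate`, `preprocess`, `train`,
`generate`, `balance`, `subsample`, `evaluate`, `benchmark` and
`degs-filter` ships at `inst/scripts/flowsynth`.

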