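---
title: "Flow-based synthesis of single-cell expression data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flow-based synthesis of single-cell expression data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Annotated scRNA-seq matrices are sparse, high-dimensional and badly
imbalanced across cell types: rare populations may contribute a few dozen
cells while the dominant type contributes thousands. Supervised cell-type
classifiers trained on such data neglect the minority classes. `flowsynth`
addresses this by fitting exact-likelihood normalizing flows to the
log-normalized expression profiles of each cell type and sampling synthetic
cells until every class reaches the third quartile of the class-size
distribution.

## The flow framework

A flow maps a data vector $x \in \mathbb{R}^d$ through a sequence of
invertible layers $h_0 = x$, $h_l = f_l(h_{l-1})$, $z = h_L$, and models the
latent $z$ as standard multivariate normal. The exact log-density follows
from the change of variables:

$$\log p_x(x) = \log p_z(z) + \sum_l \log\left|\det \frac{\partial f_l}{\partial h_{l-1}}\right|,
\qquad \log p_z(z) = -\tfrac12\left(\lVert z\rVert^2 + d\log 2\pi\right).$$

Training minimizes the mean negative log-likelihood over the training cells.
Sampling draws $z \sim N(0, I_d)$ and applies the layer inverses in reverse
order.

### MAF layer

The baseline model (`build_maffb()`) is a masked affine autoregressive flow:
$z_i = (x_i - \mu_i(x_{<i})) / \sigma_i(x_{<i})$, where the conditioner is a
one-hidden-layer ReLU network whose MADE-style binary masks guarantee that
$\mu_i, \sigma_i$ depend only on features preceding $i$. The Jacobian is
triangular, so the log-determinant is exactly $-\sum_i \log \sigma_i$.

Choices the architecture leaves open, and how we resolved them:

* **Scale positivity.** The conditioner emits $\alpha_i$ and
  $\sigma_i = e^{\alpha_i}$, making the log-determinant $-\sum_i \alpha_i$.
  This is the numerically stable standard link for this transform family.
* **Feature ordering.** Natural column order with no permutation layers for
  the single-layer default; deeper stacks draw a seeded permutation per
  extra layer so no feature is unconditionally first everywhere.
* **Conditioner depth.** One hidden ReLU layer of `hidden_features` units —
  the single width knob the architecture exposes.

### MOE-FB blocks

The richer model (`build_moefb()`) prepends a learnable *contextual feature
mask* and stacks blocks of `[ActNorm, MoE coupling, ActNorm, MAF]`:

* **Contextual feature mask.** A shallow MLP emits
  $m = 0.5\,\sigma(\cdot) \in (0, 0.5)^d$ per cell and the masked input is
  $x' = x \odot (1-m) + \bar{x}\, m$ with $\bar{x}$ the scalar mean of the
  cell's values — every feature moves at most halfway toward the cell mean,
  which softly attenuates uninformative sparse features. The map is not
  invertible and carries no Jacobian term, so we treat it as a learnable
  preprocessor: it is applied on the density/training path, excluded from
  the log-determinant, and never applied when sampling. That is the only
  reading consistent with an exact-likelihood flow, and it means generated
  cells live in the unmasked data space.
* **ActNorm.** Per-feature affine $y = s \odot x + b$ with log-determinant
  $\sum_j \log |s_j|$; identity when disabled. Initialization is
  data-dependent from the first training batch (zero mean, unit variance per
  feature on that batch), after which $s, b$ train freely.
* **MoE attention coupling.** An alternating binary mask splits features
  into a pass-through set $x_a$ and a transformed set $x_b$. Four parallel
  multi-head attention experts (10 heads each by default) process $x_a$; a
  softmax gate over a ReLU projection of $x_a$ mixes them; linear heads map
  the aggregate to $s = \tanh(\cdot)$ and $t$, and
  $z_b = x_b \odot e^s + t$ with log-determinant $\sum_{j \in b} s_j$,
  bounded by the size of the transformed set because of the tanh.
  Tokenization is feature-wise: each a-set feature is one token, linearly
  embedded to 20 dimensions, attended, and projected back to a scalar. This
  matches the module's feature-wise memory scaling — and its known
  limitation: memory grows with the square of the a-set size, which is why
  the MAF baseline remains the practical choice at very high gene counts.
  Because the embedding of a scalar token is affine in that scalar, each
  attention head reduces algebraically to a quadratic form in the feature
  values; the implementation exploits this to stay fully vectorized over
  cells, and the per-head internal key/query width is `embed_dim / n_heads`.

All gradients — through the conditioners, the attention experts, the gate,
the scale/shift heads, ActNorm and the contextual mask — are derived
analytically and verified against finite differences in the test suite.

## Training

Defaults mirror the selected reference setting: one flow layer, 1024 hidden
features, learning rate $10^{-6}$, 100 iterations. Where the protocol is
silent we chose: *iterations are epochs* over the training set; *Adam* as
the default optimizer (the selection grid fixed only the rate; plain SGD is
selectable); *batch size 256*, falling back to full batch for smaller data.
Zero-variance features (all-zero genes inside a small cell type) would
collapse the scale, so they receive tiny seeded Gaussian jitter
($\sigma = 10^{-6}$) with a warning. A non-finite loss aborts with a
condition object carrying the loss history. Training, generation, folds and
the simulator all draw their randomness from named seeds; equal seeds give
identical results.

The tests and the acceptance script use small conditioners (8–64 hidden
units) and tens of epochs at learning rates around $10^{-2}$: at fixture
scale (tens to hundreds of features) these budgets converge in seconds and
keep the whole suite fast, while the package defaults remain the reference
setting.

## Q3 balancing

`q3_plan()` computes the 0.75-quantile of the per-class cell counts by
linear interpolation and rounds half-up to an integer (the reported targets
in the source protocol are integers; with the raw label counts unavailable,
any of floor/round/ceiling would be defensible — we fixed round-half-up
once). Each class needing cells gets its own flow fitted on its own rows
only (`fit_per_type()`, which records the fitted row indices so the
benchmark can assert no test row ever reached a generator), and
`generate_balanced()` draws exactly `max(0, Q3 - observed)` cells per class,
so pooled class counts equal `max(observed, Q3)` with no overshoot.
`generate_matched()` covers the label-free protocol of drawing as many
synthetic cells as the test set holds from one flow on the full training
matrix. `proportional_subsample()` implements largest-remainder allocation
with deterministic tie-breaking (larger class first, then label order — the
protocol only says fractional adjustments are distributed, so we fixed a
reproducible rule).

## Fidelity metrics

* **WD** — per-feature 1-D Wasserstein distance via the discrete CDF sum
  over sorted unique pooled values, averaged across features; an independent
  sorted-quantile oracle cross-checks it in the tests.
* **CD** — mean absolute entrywise difference of Pearson correlation
  matrices, diagonal included (the definition is read literally);
  zero-variance columns contribute correlation 0 with a warning.
* **MMD** — biased V-statistic with the RBF kernel
  $\exp(-\lVert x-y\rVert^2 / (2\ell^2))$, averaged over the length scales
  $\{0.005, 0.01, 0.1, 0.5, 1, 2\}$. The biased form keeps
  $\mathrm{MMD}(X, X) = 0$ exactly. "Length scale" is interpreted as $\ell$;
  the report records the scales used. A linear kernel is available as an
  option.
* **Classification** — macro-averaged precision/recall/F1 (micro and
  weighted selectable and recorded); a class never predicted has precision
  defined as 0. Accuracy is the overall fraction correct.
* **Batch silhouette** — $1 - |\bar{s}|$ with silhouette widths computed
  against batch labels in Euclidean distance (widths via
  `cluster::silhouette`), averaged over samples; near 1 means well-mixed
  batches.
* **RMSE** — elementwise for same-shape arrays, or paired on the key
  intersection for keyed mean tables (for example ligand–receptor
  interaction means produced by an external inference tool), with the
  overlap size reported.

Metrics are computed in the PC-50 representation: PCA is fitted on the real
training matrix only and every other matrix is transformed with that single
fit, keeping the representation independent of the generator under
evaluation. Rank-deficient references reduce the component count with a
warning.

## The benchmark

`run_benchmark()` wires the protocol together per stratified fold (we
stratify so every type appears in every fold, which per-type generation
needs; unstratified splitting is available): fit per-type flows on training
cells, build the Q3-balanced pool, compute WD/CD/MMD between balanced-train
and test (with original-train vs test as the baseline row, using the
identical PC fit), and train a 100-tree random forest with unlimited depth
once on the original and once on the pooled cells. The forest uses `ranger`
with its Gini split criterion; an information-gain (entropy) criterion is
not available in the R random-forest implementations, and the two criteria
are near-equivalent in practice. A structural leakage audit fails hard if
any generator's recorded training rows stray outside the fold's training
indices.

`unique_top_degs()` consumes a precomputed DEG table (the differential test
itself is out of scope), filters to adjusted $p < 0.05$ and
$\log_2\mathrm{FC} > 1$, ranks by decreasing fold change (ties by smaller
adjusted $p$, then gene id — a deterministic refinement the protocol leaves
open), keeps the top 20 per type and removes genes shared by two or more
top lists.

## The simulator

`simulate_fixture()` emulates the structure the models consume: log-normal
per-gene base means; negative-binomial counts (dispersion `size = 2`, a
realistic mid-range overdispersion for droplet data); Bernoulli dropout
(default 0.3) on top of the NB zeros for the characteristic sparsity;
disjoint marker blocks per type whose means are multiplied by 4 within the
type; geometric class-size decay (default $20^{-1/3}$ per step, i.e. a 20:1
largest-to-smallest ratio over four types, the imbalance regime the
balancing protocol targets); optional per-batch log-normal multiplicative
shifts. Class sizes are one multinomial draw from the geometric
proportions. Everything hangs off a single seed.

What the simulator does **not** reproduce: real library-size variation
profiles, gene–gene co-expression modules beyond marker blocks, batch
effects with cell-type interactions, doublets, or ambient RNA. Passing the
suite therefore shows the machinery is correct and that balancing helps
under controlled imbalance; it does not certify performance on any real
tissue. Default test problem sizes (2000 cells × 200 genes, 150 HVGs kept,
2 folds) were chosen so the full simulate → preprocess → balance → classify
→ report loop runs in seconds to minutes on a single CPU.

## Numerical notes and limitations

* MAF inversion is sequential (one conditioner pass per feature rank);
  forward evaluation is a single parallel pass. Coupling and ActNorm invert
  in closed form.
* Round trips are exact to ~1e-6 at `d = 64`; analytic log-determinants
  match finite-difference Jacobians to ~1e-10 at small `d`.
* No scale clamping is applied in the MAF layer; identity initialization
  (zero output weights) plus moderate learning rates keep training stable.
  Divergence is detected and reported rather than silently clipped.
* The attention coupling's feature-wise tokens make memory quadratic in the
  a-set size; sparse or chunked attention is out of scope, so prefer
  `model = "maf"` beyond a few thousand genes.
* Conditional (label-embedding) flows, GPU execution and mixed precision
  are out of scope; per-type fitting plays the role of conditioning.
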