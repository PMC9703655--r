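---
title: "Multi-omics drug-response prediction: model, training and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omics drug-response prediction: model, training and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model omicsfusion implements, the assumptions
behind it, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, and the numerical and design choices
made where the design was genuinely open.

## Model and assumptions

The data are M omics blocks $x = \{x_m\}_{m=1}^M$ measured on a shared set
of $n_c$ cell lines, plus a partially observed $n_c \times n_d$ matrix of
log IC50 drug responses $y_{ij}$. Each block is processed by its own
feed-forward sub-network:

* embedding layer, dense $y^1_m = f({W^1_m}^\top x_m + b^1_m)$ or
  graph-masked $y^1_m = f({(W^1_m \odot A)}^\top x_m + b^1_m)$, where $A$
  is the binary PPI adjacency over the block's features. The mask is a
  hard sparsity prior: unit $j$ can only see features that interact with
  feature $j$. We set $A_{jj} = 1$ so a feature always reaches its own
  unit; without the self-loop, any feature absent from the interactome
  would be silenced entirely, which cannot be the intent of a prior that
  merely restricts cross-feature mixing. Graph embeddings keep the input
  width; dense embeddings may change it.
* a hidden dense layer $y^2_m = f({W^2_m}^\top y^1_m + b^2_m)$ with
  per-omics width, and
* a linear head of width $n_f = n_d$ holding that block's per-drug
  predictions.

The head width must equal the drug count because fusion uses a kill
matrix $k(d,i) = [d{=}i]$: normalized attention weights

$$W(d,m,i) = \frac{e^{W^3(d,m,i)}\,k(d,i)}{\sum_m e^{W^3(d,m,i)}}$$

make drug $d$'s output $y_d = g\!\left(\sum_m W(d,m,d)\, y^2_{m,d} + b_d\right)$
a *convex combination* of the per-omics predictions for that same drug, so
no drug's output is influenced by another drug's head position. The
per-omics hidden widths (64/32/128/…) differ from the drug count while
the kill matrix needs equal indices; we reconcile the two by keeping the
hidden widths and adding the linear per-drug head as a third, separate
layer. The attention dimension $M \cdot n_f$ is
derived, never configured.

Hidden activation $f$ is the rectifier and the output activation $g$ is
the identity (a regression on log IC50); this also makes the
convex-combination property exact, which the test suite exploits.

The attention *score* of omics $m$ for drug $d$ is
$\mathrm{score}(m,d) = \sum_i W(d,m,i) = W(d,m,d)$; columns sum to one, so
scores read directly as per-drug mixture proportions.

## Training procedure

Both stages minimize the mean squared error over *observed* responses
(missing entries are masked out of the loss rather than dropping whole
cell lines) with Adam at learning rate 0.001.

* **Stage 1** trains each sub-network alone to predict all $n_d$ drugs
  from its block: 200 epochs for graph-embedded blocks, 1000 for dense
  ones (graph masks shrink the effective parameter count, and convergence
  is correspondingly faster).
* **Stage 2** freezes every sub-network parameter — asserted bit-identical
  before and after on every run — and learns only the raw attention
  weights $W^3$ (their kill-matrix diagonal slice; no other entry can
  affect the output) and the output bias, for 200 epochs. $W^3$ starts at
  zero, i.e. uniform attention over omics, so the learned specialization
  is the departure from an unweighted fusion. Sub-network weights use
  Glorot-uniform initialization; all biases start at zero.

**Batch size.** The default is minibatches of 32. With the fixed epoch
budgets above, full-batch training would perform only 200–1000 optimizer
steps; Adam moves parameters by roughly the learning rate per step, so
neither the sub-networks nor the softmax attention (which needs raw-weight
differences of order $\log$-odds to express concentrated scores) can reach
convergence in that many steps. Full-batch remains available
(`batch_size = NULL`) and is what the monotone-descent property test uses.

**Early stopping.** By default each sub-network picks its epoch count by
the loss on a 10% validation split and is then refit on all training rows
for exactly that many epochs. This is load-bearing for the two-stage
scheme, not a cosmetic regularizer: stage 2 fits the attention weights on
the same cells stage 1 trained on, so a sub-network that memorizes its
training responses looks *best* exactly where the attention is learned,
and fusion locks onto the worst-generalizing block. With epoch selection
in place, the relative quality of the frozen heads on the training cells
reflects their held-out quality and the attention stage rewards the right
block.

**Dropout** (inverted, rates per omics: 0.2 for expression, mutation and
metabolomics; 0.4 for CNV and RPPA) is applied after the embedding
activation only. Applying a second dropout after the hidden layer was
evaluated and consistently worsened held-out error of the graph
sub-networks without reducing overfitting beyond what embedding dropout
and epoch selection already achieve; the parameter container still
supports both rates.

**Divergence** (a non-finite loss) raises an error naming the epoch.
Training is fully deterministic given the config seed: initialization,
shuffling, dropout masks and fold assignment all derive from it.

## Preprocessing

* Features that are exactly zero in **strictly more than** 95% of cell
  lines are removed (the same predicate for continuous and integer
  blocks; for mutation/CNV matrices "zero" means "no event"). The strict
  inequality also applies to drug selection: drugs are kept when observed
  on strictly more than 95% of cell lines, or the `k` highest-coverage
  drugs with ties broken by drug id.
* Standardization is per feature, $(x - \bar x)/s$ with the sample
  standard deviation ($n-1$); constant features get scale 1 rather than
  being dropped (the zero-fraction filter has already run). Statistics
  are always fit on training cells only and applied to held-out cells:
  per-fold fitting is the conservative, leakage-free choice.
* Cell lines are aligned across blocks and responses by sorted
  intersection of ids, so fold splits are reproducible and invariant to
  block order.
* The PPI adjacency is built per block from the edge list restricted to
  the block's features, symmetric with unit diagonal; features without
  interactions keep only their self-loop.

## Synthetic data: what it emulates, what it does not

`simulation_config()` defaults describe a scaled-down pan-cancer panel:
522 cell lines, 22 drugs, five blocks (expression 120, mutation 80, CNV
80, RPPA 40, metabolomics 45 features), an Erdős–Rényi interactome with
edge probability 0.05 over the gene universe, mutation dominance 0.9,
response noise sd 0.3, 5% missing responses. Continuous blocks are
standard normal, mutations Bernoulli(0.1) indicators, CNV integer copy
counts centred at 2. Per drug and block, a sparse coefficient vector (10%
of features) defines a linear score — computed from adjacency-smoothed
features when `graph_signal` is set, so responses genuinely depend on
interactome neighbours — centred and scaled to unit variance; responses
are the share-weighted sum of scores plus Gaussian noise.

The linear ground truth is deliberate: recovery has closed-form oracles
(ordinary least squares on noiseless data, ridge regression in general),
so the network can be judged against an independent reference rather than
against itself. The generator does **not** emulate real CCLE marginal
distributions, copy-number segment structure, batch effects, or
correlated drug classes; passing tests show the machinery recovers
planted structure under the stated noise, not that it reproduces
biological findings on real panels.

Because the fusion is a per-drug convex combination of heads, its best
attainable $R^2$ under dominance $d < 1$ sits below an unconstrained
regression on all blocks (at dominance 0.9 the asymptotic ceiling is
about 0.83 versus 0.92); the ridge comparison in the acceptance checks is
therefore tight by construction, and the interesting quantity is the gap,
not the absolute value.

## Numerical choices

* Softmax normalization subtracts the per-(d, i) maximum before
  exponentiating, so raw weights of $\pm 50$ (and beyond) stay exactly
  normalized; results equal the naive formula to machine precision
  whenever the latter does not overflow.
* Text serialization writes doubles with 17 significant digits
  (`%.17g`), which round-trips IEEE doubles exactly — checkpoint
  save/load reproduces the forward pass bit-identically, and the
  write/read cycle of every table format is exact.
* Ranking ties (equal log IC50 or equal predictions in Top-k, equal
  per-drug MSE) are broken by drug id, lexically, for determinism.
* Per-drug $R^2$ uses the evaluated set's own per-drug mean; drugs with
  constant or insufficient observed truths are excluded with a warning.
  Cross-validated aggregates are unweighted mean ± sample sd over folds.
* The ridge reference (`ridge_baseline()`) is the per-drug closed form
  $(X^\top X + \lambda I)^{-1} X^\top y$ on centred responses with
  $\lambda = 1$, the common library default for standardized features.

## Problem sizes used by the test suite

The acceptance computations simulate 600 cell lines with three blocks
(expression 120, mutation 80, metabolomics 45; mutation dominant at 0.9,
noise sd 0.3) and run three-fold cross-validation plus the ablation over
all seven block combinations; unit and property tests use panels of
40–240 cells with reduced epoch budgets. These sizes were chosen so the
planted structure is identifiable with comfortable margin while the whole
suite stays desk-scale.

## Known limitations

* The two-stage scheme never fine-tunes sub-networks jointly with the
  attention; a block that is only useful *in combination* with another
  will be under-weighted.
* Attention is applied only at the output layer, and fusion is convex per
  drug — it cannot express "block A minus block B" corrections.
* Identifiers must already agree across files; there is no id mapping,
  batch correction, or imputation of missing omics blocks.
* The CLI and checkpoint formats target reproducibility, not streaming
  scale; parameters are stored as plain text.
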