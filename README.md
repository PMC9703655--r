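# omicsfusion

Anticancer drug-response prediction from multi-omics cell-line profiles
with interactome-masked embeddings and kill-matrix attention fusion.

## The problem

Cancer cell lines respond very differently to the same drug, and panels
such as CCLE/GDSC characterize each line by several omics layers — mRNA
expression, gene mutations, copy-number variation (CNV), RPPA protein
expression and metabolomics — together with log IC50 drug-sensitivity
measurements (lower log IC50 = more effective drug). The modelling
questions this package addresses are: how to regress log IC50 on
heterogeneous, high-dimensional omics blocks with few samples; how to use
a protein–protein interaction (PPI) network as prior structure; and how to
fuse the blocks so that their relative contribution per drug is both
learned and interpretable.

## The model

Each omics block m (features x_m, dimension n_m) has its own sub-network:

- **Embedding layer.** Dense: `y¹_m = f(W¹_mᵀ x_m + b¹_m)`. Graph: the
  weight matrix is elementwise-masked by the binary PPI adjacency A,
  `y¹_m = f((W¹_m ⊙ A)ᵀ x_m + b¹_m)`, so hidden unit j receives input only
  from features that interact with feature j (A is symmetric, unit
  diagonal). For graph embeddings the layer width equals n_m.
- **Hidden dense layer** `y²_m = f(W²_mᵀ y¹_m + b²_m)` with per-omics
  widths, f = rectifier, followed by a **linear head** of width
  n_f = n_d (the drug count), giving that block's per-drug predictions.
- **Attention fusion.** The heads are concatenated (`z`, length M·n_f) and
  combined with softmax weights under a *kill matrix* k(d,i) = [d = i]:

      W(d,m,i) = exp(W³(d,m,i)) · k(d,i) / Σ_m exp(W³(d,m,i))

  so drug d's output, `y_d = Σ_m W(d,m,d) · z_{m,d} + b_d`, is a convex
  combination of the per-omics predictions for that drug. The summed
  weights `score(m,d) = Σ_i W(d,m,i) = W(d,m,d)` are the per-omics
  attention scores (columns sum to 1).

Training is two-stage with masked mean-squared-error loss over observed
responses and the Adam optimizer (learning rate 0.001): stage 1 fits each
sub-network alone against all drugs; stage 2 freezes every sub-network
parameter and learns only the attention weights and output bias.

Evaluation statistics: masked MSE, per-drug-averaged R²
(`R² = (1/n_d) Σ_j [1 − SSres_j / SStot_j]`), and Top-k drug accuracy (the
rate at which the truly most effective drug — lowest observed log IC50 —
appears among the k lowest predicted values).

A seeded synthetic generator plants known structure (an Erdős–Rényi
interactome, sparse drug-specific linear signals, a designated dominant
omics block carrying a chosen share of the response variance, Gaussian
noise, missing responses), so fusion, attention recovery and ablation are
testable end-to-end without downloads.

## Worked example

```r
library(omicsfusion)
sim <- simulate_dataset(simulation_config(
  n_cells = 200, n_drugs = 8,
  feature_counts = c(expression = 40, mutation = 30, metabolomics = 20),
  dominant_omics = "mutation", seed = 1))
cfg <- training_config(seed = 1, n_folds = 3)
cv  <- cross_validate(sim$dataset, cfg)
print(cv$aggregate, digits = 3)
#>   metric   mean     sd
#> 1    mse  0.666 0.0352
#> 2     r2  0.381 0.0321
#> 3   top1 44.512 2.5994
#> 4   top3 82.007 2.5164
round(rowMeans(cv$attention$mean), 3)
#>   expression     mutation metabolomics
#>        0.147        0.698        0.155
```

The generator planted 90% of the response signal in the mutation block;
three-fold cross-validation reports held-out MSE/R² and Top-1/Top-3
accuracy, and the attention scores recover the mutation block as the main
contributor. Larger panels (more cells, the defaults of
`simulation_config()`) sharpen both the R² and the attention contrast.

Other entry points: `ablation_run()` scores every omics combination
(stage-1 sub-networks reused, one attention stage per subset, table sorted
by MSE), `save_checkpoint()`/`load_checkpoint()` give bit-exact model
round-trips, `attention_report()` writes the score TSV and heatmap, and
`cmd_simulate`/`cmd_train`/`cmd_evaluate`/`cmd_ablate` (wrapped by
`inst/cli/omicsfusion.R`) drive the same pipeline from files.

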