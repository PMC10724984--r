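# pathvae

Integration of multi-batch single-cell RNA-seq data into an
**interpretable latent space in which every dimension is a biological
pathway**.

## The problem

Cells measured by different platforms, labs or runs carry systematic
technical variation (batch effects) that obscures biological identity.
Integration methods project cells from all batches into a shared
embedding where proximity reflects cell type, not platform — but most
deep-learning integrators produce latent axes with no meaning, so the
embedding cannot be read biologically.

`pathvae` addresses both problems at once with a knowledge-regularized
conditional variational autoencoder:

* the **encoder** (a one-hidden-layer MLP receiving the log-normalized
  expression of a cell plus a one-hot batch indicator) outputs the
  posterior `N(μ, σ²)` over a latent vector `z` with **one dimension per
  pathway** of a gene-set knowledge base (GMT format, e.g. MSigDB or
  WikiPathways collections);
* the **decoder is a single linear layer**, `x' = z w_D + b + o_batch`,
  with a learned per-batch per-gene offset, so each entry of `w_D`
  (P pathways × G genes) is directly the contribution of a gene to a
  pathway;
* training maximizes the ELBO

  `L = E_q(z|x)[log p(x|z)] − β · KL(q(z|x) ‖ N(0, I))`

  (Gaussian reconstruction, closed-form KL) plus a **knowledge penalty**
  `λ · ‖w_D − Â‖` (L1 or L2) that pulls the decoder weights toward the
  binary pathway–gene adjacency matrix `Â`; the adjacency can also be
  applied as a hard structural **mask** on the decoder (and optionally
  the encoder) instead of a penalty.

Because the penalty drives in-pathway weights toward 1 and off-pathway
weights toward 0, the latent axes align with the pathways, the posterior
mean `μ` becomes a table of per-cell **pathway activities**, and genes
with large decoder weight *outside* the prior are candidate new pathway
members.

The package also ships the full surrounding workflow: the standard
preprocessing recipe (cell filter ≥ 600 expressed genes, gene filter
≥ 3 cells, median-count normalization, `log1p`, top-2000
highly-variable-gene selection by binned normalized dispersion);
integration metrics (ARI, NMI, cell-type ASW rescaled to `[0, 1]`,
isolated-label F1, silhouette); cross-batch KNN label transfer with
confusion matrices; pathway-subset embeddings and decoder-weight gene
rankings; and a negative-binomial multi-batch count simulator with
known ground truth plus robustness perturbations (binomial count
downsampling, cell subsampling, per-batch cell-type holdout).

## Worked example

Simulate a two-batch, four-type dataset with 10 ground-truth pathway
programs, preprocess it, train, and evaluate the integration:

```r
library(pathvae)

truth <- make_truth(seed = 1)          # 10 pathways x 200 genes, 4 types, 2 batches
X     <- simulate_counts(truth, n_cells_per_type_per_batch = 50, seed = 2)
Xp    <- run_pipeline(X, min_genes = 50, min_cells = 3, n_top = 200)

dir <- tempfile(); write_fixture(truth, X, dir)
A   <- build_adjacency(parse_gmt(file.path(dir, "pathways.gmt")), gene_symbols(Xp))

model <- fit_pathvae(Xp, A, train_config(epochs = 150, minibatch_size = 64, seed = 7))
emb   <- transform_cells(model, Xp)    # cells x pathways, posterior means

evaluate_all(emb, Xp$celltype, Xp$batch)
#> <metrics_report>
#>   ari           1.0000
#>   nmi           1.0000
#>   asw_celltype  0.7664
#>   isolated_f1   1.0000
#>   silhouette    0.5328
```

k-means on the 10-dimensional pathway embedding recovers the four cell
types perfectly (ARI = NMI = 1), while the mean batch-label silhouette
drops from 0.093 on the log-normalized data to 0.043 on the embedding —
batches mix, biology separates. The decoder weights recover the
generating pathway structure:

```r
rank_genes_for_pathway(model, "PATHWAY_02", top_k = 5, mode = "absolute")
#>   rank  gene    weight in_prior
#> 1    1 G0148 0.9649835     TRUE
#> 2    2 G0163 0.9608265     TRUE
#> 3    3 G0033 0.9607992     TRUE
#> 4    4 G0190 0.9590085     TRUE
#> 5    5 G0070 0.9579652     TRUE
```

In-pathway weights sit near 1 (the value the distance penalty targets);
`in_prior = FALSE` rows at high rank flag putative new pathway members.

A thin command-line wrapper over the same functions is installed at
`system.file("cli", "pathvae", package = "pathvae")` with subcommands
`simulate`, `preprocess`, `train`, `integrate`, `evaluate`, `annotate`,
`interpret` and flags `--config`, `--seed`, `--outdir`,
`--knowledge-mode`, `--lambda-k`, `--epochs`.

## Documentation

See the methods vignette (`vignettes/pathway-regularized-vae.Rmd`) for
the model, its assumptions, the tunable parameters, what the synthetic
generator does and does not emulate, and known limitations.
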