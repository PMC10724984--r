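# Shared fixtures and independent oracles for the test suite.

# Area under the ROC curve via the rank (Mann-Whitney) statistic.
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  r <- rank(scores)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Exhaustive pair-counting adjusted Rand index: enumerates all C(n,2)
# item pairs and applies the RI/E(RI)/max(RI) adjustment directly.
# Independent of the contingency-table closed form under test.
ari_pair_counting <- function(truth, pred) {
  n <- length(truth)
  pairs <- utils::combn(n, 2)
  same_c <- truth[pairs[1, ]] == truth[pairs[2, ]]
  same_k <- pred[pairs[1, ]] == pred[pairs[2, ]]
  a <- sum(same_c & same_k)          # together in both
  b <- sum(!same_c & !same_k)        # apart in both
  n_pairs <- ncol(pairs)
  # pair-level expectation/maximum of the "a" count given the margins
  sum_a <- sum(same_c)
  sum_b <- sum(same_k)
  expected <- sum_a * sum_b / n_pairs
  maximum <- (sum_a + sum_b) / 2
  if (abs(maximum - expected) < 1e-12) return(1)
  (a - expected) / (maximum - expected)
}

# First epoch at which the reconstruction loss is within 5% of its final
# value.
epochs_to_converge <- function(history, tol = 0.05) {
  final <- utils::tail(history$reconstruction, 1)
  which(history$reconstruction <= (1 + tol) * final)[1]
}

# The default synthetic study: P=10 pathways, G=200 genes, T=4 types,
# B=2 batches, 50 cells/type/batch; trained once per session and shared
# across tests (150 epochs, minibatch 64 -- a few seconds of CPU).
.fixture_cache <- new.env(parent = emptyenv())

default_fixture <- function() {
  if (!is.null(.fixture_cache$fx)) return(.fixture_cache$fx)
  truth <- make_truth(seed = 1)
  X <- simulate_counts(truth, n_cells_per_type_per_batch = 50, seed = 2)
  Xp <- run_pipeline(X, min_genes = 50, min_cells = 3, n_top = 200)
  dir <- tempfile("fixture")
  write_fixture(truth, X, dir)
  A <- build_adjacency(parse_gmt(file.path(dir, "pathways.gmt")),
                       gene_symbols(Xp), min_overlap = 5)
  .fixture_cache$fx <- list(truth = truth, X = X, Xp = Xp, A = A, dir = dir)
  .fixture_cache$fx
}

fixture_train_config <- function(knowledge_mode = "l2", seed = 7, ...) {
  train_config(knowledge_mode = knowledge_mode, epochs = 150,
               minibatch_size = 64, seed = seed, ...)
}

trained_model <- function(mode = "l2") {
  key <- paste0("model_", mode)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  fx <- default_fixture()
  .fixture_cache[[key]] <- fit_pathvae(fx$Xp, fx$A,
                                       fixture_train_config(mode))
  .fixture_cache[[key]]
}

# AUROC of absolute decoder weights against the generating adjacency.
recovery_auroc <- function(model, fx = default_fixture()) {
  w <- abs(decoder_weights(model))
  a_true <- fx$truth$A_true[rownames(w), colnames(w)]
  auroc(as.vector(w), as.vector(a_true))
}

# k-means ARI of an embedding against cell-type labels, fixed seed.
kmeans_ari <- function(embedding, celltype, seed = 0) {
  k <- length(unique(as.character(celltype)))
  withr::with_seed(seed, {
    cl <- stats::kmeans(embedding, centers = k, nstart = 10,
                        iter.max = 100)$cluster
    adjusted_rand_index(celltype, cl)
  })
}

# The perfect-separation embedding: 4 cell types over 2 batches, one type
# present in only one batch, every type a tight cluster far from all
# others.
perfect_separation_fixture <- function(n_per = 25, spread = 0.1,
                                       center_dist = 100, seed = 11) {
  withr::with_seed(seed, {
    centers <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1) * center_dist,
                      ncol = 2, byrow = TRUE)
    types <- c("typeA", "typeB", "typeC", "typeD")
    emb <- do.call(rbind, lapply(1:4, function(t) {
      sweep(matrix(stats::rnorm(2 * n_per, sd = spread), ncol = 2),
            2, centers[t, ], "+")
    }))
    celltype <- rep(types, each = n_per)
    # typeD exists only in batch1; other types split across both batches
    batch <- rep(c("batch1", "batch2"), length.out = 4 * n_per)
    batch[celltype == "typeD"] <- "batch1"
    list(embedding = emb, celltype = celltype, batch = batch)
  })
}
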