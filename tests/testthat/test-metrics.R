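test_that("ARI endpoint identities and hand-traced values hold", {
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  # invariance to label renaming
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1)
  # crossed partition of 4 items (exhaustive pair counting gives -0.5)
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(0, 1, 0, 1)), -0.5)
  expect_error(adjusted_rand_index(1:3, 1:4), "length")
})

test_that("contingency-form ARI equals exhaustive pair counting on random labelings", {
  withr::local_seed(21)
  for (trial in 1:60) {
    n <- sample(3:12, 1)
    truth <- sample(1:sample(2:4, 1), n, replace = TRUE)
    pred <- sample(1:sample(2:4, 1), n, replace = TRUE)
    expect_equal(adjusted_rand_index(truth, pred),
                 ari_pair_counting(truth, pred),
                 label = paste("trial", trial))
  }
})

test_that("ARI agrees with the reference implementation in mclust", {
  skip_if_not_installed("mclust")
  withr::local_seed(22)
  for (trial in 1:20) {
    truth <- sample(1:3, 40, replace = TRUE)
    pred <- sample(1:4, 40, replace = TRUE)
    expect_equal(adjusted_rand_index(truth, pred),
                 mclust::adjustedRandIndex(truth, pred))
  }
})

test_that("NMI matches the entropy-decomposition route and its endpoints", {
  expect_equal(normalized_mutual_info(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(normalized_mutual_info(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  expect_warning(v <- normalized_mutual_info(c(1, 1, 1), c(1, 2, 3)),
                 "single category")
  expect_equal(v, 0)
  expect_equal(normalized_mutual_info(c(1, 1), c(2, 2)), 1)

  # independent route: I = H(P) + H(T) - H(P,T) by direct summation
  withr::local_seed(23)
  for (trial in 1:20) {
    n <- 30
    truth <- sample(1:3, n, replace = TRUE)
    pred <- sample(1:3, n, replace = TRUE)
    ent <- function(tab) { p <- tab[tab > 0] / n; -sum(p * log(p)) }
    hx <- ent(table(truth)); hy <- ent(table(pred))
    hxy <- ent(table(truth, pred))
    expect_equal(normalized_mutual_info(truth, pred),
                 (hx + hy - hxy) / sqrt(hx * hy))
  }
})

test_that("ARI and NMI are invariant to joint cell reordering and code renaming", {
  withr::local_seed(24)
  truth <- sample(letters[1:3], 50, replace = TRUE)
  pred <- sample(1:4, 50, replace = TRUE)
  perm <- sample(50)
  recode <- c(a = "z", b = "y", c = "x")
  expect_equal(adjusted_rand_index(recode[truth[perm]], pred[perm] * 7),
               adjusted_rand_index(truth, pred))
  expect_equal(normalized_mutual_info(recode[truth[perm]], pred[perm] * 7),
               normalized_mutual_info(truth, pred))
})

test_that("silhouette matches the hand-computed two-cluster fixture", {
  emb <- matrix(c(0, 1, 10, 11), 4, 1)
  labels <- c("a", "a", "b", "b")
  s <- silhouette_per_cell(emb, labels)
  # cell at 0: a = 1, b = (10 + 11)/2 = 10.5 -> 9.5/10.5
  expect_equal(s[1], 9.5 / 10.5)
  expect_equal(mean(s), mean(c(9.5 / 10.5, 8.5 / 9.5, 8.5 / 9.5, 9.5 / 10.5)))
  expect_equal(round(mean(s), 3), 0.9)

  # two fully coincident point clusters: a = b = 0 -> 0 by convention
  emb2 <- matrix(0, 8, 1)
  expect_equal(mean(silhouette_per_cell(emb2, rep(c("a", "b"), each = 4))), 0)

  expect_error(silhouette_per_cell(emb, rep("a", 4)), "2 clusters")
  # singleton cluster convention
  s3 <- silhouette_per_cell(matrix(c(0, 1, 9), 3, 1), c("a", "a", "b"))
  expect_equal(s3[3], 0)
})

test_that("silhouette agrees with the cluster package on random data", {
  skip_if_not_installed("cluster")
  withr::local_seed(25)
  emb <- matrix(rnorm(60), 30, 2)
  labels <- sample(1:3, 30, replace = TRUE)
  ref <- cluster::silhouette(labels, stats::dist(emb))[, "sil_width"]
  expect_equal(silhouette_per_cell(emb, labels), unname(ref))
})

test_that("asw_celltype is the affine rescaling of mean silhouette", {
  withr::local_seed(26)
  emb <- matrix(rnorm(40), 20, 2)
  labels <- rep(c("a", "b"), 10)
  expect_equal(asw_celltype(emb, labels),
               (1 + mean(silhouette_per_cell(emb, labels))) / 2)
  # near-perfectly separated tight clusters approach 1; coincident give 1/2
  far <- rbind(matrix(rnorm(20, sd = 1e-3), 10, 2),
               matrix(rnorm(20, 100, sd = 1e-3), 10, 2))
  expect_gt(asw_celltype(far, rep(c("a", "b"), each = 10)), 0.99)
})

test_that("isolated-label F1 is 1 for pure isolated clusters and 2/3 for an even split", {
  fx <- perfect_separation_fixture()
  expect_identical(isolated_labels(fx$celltype, fx$batch), "typeD")
  expect_equal(isolated_label_f1(fx$embedding, fx$celltype, fx$batch), 1)

  # isolated type split across two distant pure clusters: precision 1,
  # recall 1/2, F1 = 2/3
  withr::local_seed(27)
  mk <- function(cx, cy, n) cbind(rnorm(n, cx, 0.05), rnorm(n, cy, 0.05))
  emb <- rbind(mk(0, 0, 20), mk(100, 100, 20), mk(0, 100, 10), mk(100, 0, 10))
  ct <- c(rep("A", 20), rep("B", 20), rep("C", 20))
  ba <- c(rep(c("b1", "b2"), 20), rep("b1", 20))
  expect_identical(isolated_labels(ct, ba), "C")
  expect_equal(isolated_label_f1(emb, ct, ba), 2 / 3)

  # when no label is batch-restricted, all tie as isolated; still defined
  expect_identical(sort(isolated_labels(rep(c("A", "B"), 10),
                                        rep(c("b1", "b2"), each = 10))),
                   c("A", "B"))
  val <- isolated_label_f1(fx$embedding[fx$celltype != "typeD", ],
                           fx$celltype[fx$celltype != "typeD"],
                           fx$batch[fx$celltype != "typeD"])
  expect_true(val >= 0 && val <= 1)

  expect_error(isolated_label_f1(fx$embedding, fx$celltype, NULL),
               "batch")
})

test_that("evaluate_all bundles the five metrics with their ranges", {
  fx <- perfect_separation_fixture()
  rep_ <- evaluate_all(fx$embedding, fx$celltype, fx$batch, seed = 1)
  expect_s3_class(rep_, "metrics_report")
  expect_equal(rep_$ari, 1)
  expect_equal(rep_$nmi, 1)
  expect_equal(rep_$isolated_f1, 1)
  expect_gt(rep_$asw_celltype, 0.99)
  expect_true(rep_$silhouette >= -1 && rep_$silhouette <= 1)

  tab <- metrics_as_table(rep_, method = "toy")
  expect_identical(nrow(tab), 5L)
  expect_identical(tab$method, rep("toy", 5))
})
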