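#' Adjusted Rand index
#'
#' Chance-adjusted pair-counting agreement between two labelings,
#' `ARI = (RI - E[RI]) / (max(RI) - E[RI])`, computed via the standard
#' contingency-table closed form with the hypergeometric expectation.
#' Symmetric and invariant to renaming of categories.  Returns 1 for the
#' degenerate cases (both labelings a single category, or both all
#' singletons) where the adjustment denominator vanishes and the
#' partitions are identical.
#'
#' @param truth,pred Per-cell categorical labels of equal length.
#' @return Scalar in `[-1, 1]`; 1 iff the partitions coincide.
#' @export
adjusted_rand_index <- function(truth, pred) {
  if (length(truth) != length(pred))
    stop("labelings differ in length (", length(truth), " vs ",
         length(pred), ")")
  n <- length(truth)
  tab <- table(truth, pred)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maximum <- (sum_a + sum_b) / 2
  if (abs(maximum - expected) < .Machine$double.eps * max(1, maximum))
    return(1)  # both trivial partitions: identical by construction
  (sum_ij - expected) / (maximum - expected)
}

#' Normalized mutual information
#'
#' `NMI = I(P; T) / sqrt(H(P) H(T))`: mutual information of the joint
#' category distribution normalized by the geometric mean of the Shannon
#' entropies.  If either labeling has a single category the normalizer is
#' zero; the function then returns 1 when both labelings are identical
#' single-category partitions and 0 (with a warning) otherwise.
#'
#' @param truth,pred Per-cell categorical labels of equal length.
#' @return Scalar in `[0, 1]`.
#' @export
normalized_mutual_info <- function(truth, pred) {
  if (length(truth) != length(pred))
    stop("labelings differ in length")
  n <- length(truth)
  tab <- table(truth, pred)
  pij <- tab / n
  pi_ <- rowSums(pij)
  pj_ <- colSums(pij)
  hx <- -sum(ifelse(pi_ > 0, pi_ * log(pi_), 0))
  hy <- -sum(ifelse(pj_ > 0, pj_ * log(pj_), 0))
  if (hx == 0 || hy == 0) {
    if (hx == 0 && hy == 0) return(1)
    warning("one labeling has a single category; NMI undefined, returning 0")
    return(0)
  }
  outer_p <- outer(pi_, pj_)
  nz <- pij > 0
  i_pt <- sum(pij[nz] * log(pij[nz] / outer_p[nz]))
  as.numeric(i_pt / sqrt(hx * hy))
}

#' Per-cell silhouette scores
#'
#' `s_i = (b - a) / max(a, b)` where `a` is the mean distance from cell i
#' to the other members of its own cluster and `b` the smallest mean
#' distance to any other cluster.  Cells in singleton clusters get 0 by
#' convention.
#'
#' @param embedding Numeric matrix, cells x dimensions.
#' @param labels Per-cell cluster labels; at least two clusters required.
#' @param metric Distance metric name passed to [stats::dist()]
#'   (default `"euclidean"`).
#' @return Numeric vector of per-cell scores in `[-1, 1]`.
#' @export
silhouette_per_cell <- function(embedding, labels, metric = "euclidean") {
  embedding <- as.matrix(embedding)
  labels <- as.character(labels)
  if (nrow(embedding) != length(labels))
    stop("need one label per embedding row")
  lv <- unique(labels)
  if (length(lv) < 2)
    stop("silhouette requires at least 2 clusters (got ", length(lv), ")")
  d <- as.matrix(stats::dist(embedding, method = metric))
  sizes <- table(labels)
  s <- numeric(nrow(embedding))
  # mean distance from every cell to every cluster, in one pass
  memb <- vapply(lv, function(l) as.numeric(labels == l), numeric(length(labels)))
  sums <- d %*% memb                      # cells x clusters: summed distances
  for (i in seq_len(nrow(embedding))) {
    li <- labels[i]
    ni <- sizes[[li]]
    if (ni == 1) { s[i] <- 0; next }
    a <- sums[i, match(li, lv)] / (ni - 1)
    others <- lv[lv != li]
    b <- min(sums[i, match(others, lv)] / as.numeric(sizes[others]))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  s
}

#' Cell-type average silhouette width rescaled to [0, 1]
#'
#' `ASW = (1 + mean silhouette(cell type)) / 2`, so 1 means perfectly
#' compact, separated cell types and 0 the reverse.
#'
#' @param embedding Numeric matrix, cells x dimensions.
#' @param celltype_labels Per-cell cell-type labels.
#' @param metric Distance metric (default Euclidean).
#' @return Scalar in `[0, 1]`.
#' @export
asw_celltype <- function(embedding, celltype_labels, metric = "euclidean") {
  (1 + mean(silhouette_per_cell(embedding, celltype_labels, metric))) / 2
}

# Labels present in the fewest batches; ties keep all tied labels (when
# every label is present in all batches, all count as isolated).
isolated_labels <- function(celltype_labels, batch_labels) {
  ct <- as.character(celltype_labels)
  ba <- as.character(batch_labels)
  presence <- tapply(ba, ct, function(b) length(unique(b)))
  names(presence)[presence == min(presence)]
}

#' Isolated-label F1
#'
#' Measures preservation of dataset-specific cell types.  Isolated labels
#' are the cell types present in the fewest batches.  The embedding is
#' clustered by k-means over a grid of cluster counts; for each isolated
#' label the F1 score is computed treating each cluster (in each
#' clustering) as the predicted-positive set, and the maximum over
#' clusters and grid values is kept.  The final score is the mean over
#' isolated labels; 1 means every dataset-specific type is captured as its
#' own separate cluster.
#'
#' @param embedding Numeric matrix, cells x dimensions.
#' @param celltype_labels Per-cell cell-type labels.
#' @param batch_labels Per-cell batch labels (required: isolation is
#'   defined by batch presence).
#' @param k_grid Integer vector of cluster counts; default
#'   `max(2, T-2) ... T+2` for T cell types.
#' @param seed Seed for the k-means initializations (default 0).
#' @return Scalar in `[0, 1]`.
#' @export
isolated_label_f1 <- function(embedding, celltype_labels, batch_labels,
                              k_grid = NULL, seed = 0) {
  if (is.null(batch_labels) || length(batch_labels) == 0)
    stop("batch labels are required: isolation is defined by batch presence")
  embedding <- as.matrix(embedding)
  ct <- as.character(celltype_labels)
  stopifnot(nrow(embedding) == length(ct),
            length(ct) == length(batch_labels))
  iso <- isolated_labels(ct, batch_labels)
  n_types <- length(unique(ct))
  if (is.null(k_grid))
    k_grid <- seq(max(2, n_types - 2), n_types + 2)
  k_grid <- k_grid[k_grid >= 2 & k_grid <= nrow(embedding) - 1]
  if (length(k_grid) == 0) stop("no feasible cluster count in k_grid")

  best <- stats::setNames(rep(0, length(iso)), iso)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  for (k in k_grid) {
    cl <- stats::kmeans(embedding, centers = k, nstart = 10,
                        iter.max = 100)$cluster
    for (lab in iso) {
      truth_pos <- ct == lab
      for (c_id in unique(cl)) {
        pred_pos <- cl == c_id
        tp <- sum(truth_pos & pred_pos)
        if (tp == 0) next
        prec <- tp / sum(pred_pos)
        rec <- tp / sum(truth_pos)
        f1 <- 2 * prec * rec / (prec + rec)
        if (f1 > best[[lab]]) best[[lab]] <- f1
      }
    }
  }
  mean(best)
}

#' Compute the full integration metrics report
#'
#' ARI and NMI compare cell-type labels with a k-means clustering of the
#' embedding (k = number of cell types, fixed seed); ASW and the mean
#' silhouette use the cell-type labels directly; isolated-label F1 uses
#' the batch labels.  The clustering configuration is recorded in the
#' report so a different clustering can be substituted.
#'
#' @param embedding Numeric matrix, cells x dimensions.
#' @param celltype_labels,batch_labels Per-cell labels.
#' @param k Number of k-means clusters for ARI/NMI (default: number of
#'   cell types).
#' @param seed Seed for all clustering (default 0).
#' @return Object of class `metrics_report`: list with `ari`, `nmi`,
#'   `asw_celltype`, `isolated_f1`, `silhouette` and `config`.
#' @export
evaluate_all <- function(embedding, celltype_labels, batch_labels,
                         k = NULL, seed = 0) {
  embedding <- as.matrix(embedding)
  ct <- as.character(celltype_labels)
  if (is.null(k)) k <- length(unique(ct))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  cl <- stats::kmeans(embedding, centers = k, nstart = 10,
                      iter.max = 100)$cluster
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  sil <- silhouette_per_cell(embedding, ct)
  structure(
    list(ari = adjusted_rand_index(ct, cl),
         nmi = normalized_mutual_info(ct, cl),
         asw_celltype = (1 + mean(sil)) / 2,
         isolated_f1 = isolated_label_f1(embedding, ct, batch_labels,
                                         seed = seed),
         silhouette = mean(sil),
         config = list(clustering = "kmeans", k = k, seed = seed,
                       metric = "euclidean")),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  for (m in c("ari", "nmi", "asw_celltype", "isolated_f1", "silhouette"))
    cat(sprintf("  %-13s %.4f\n", m, x[[m]]))
  invisible(x)
}

#' Flatten a metrics report for benchmarking tables
#'
#' @param x A `metrics_report`.
#' @param ... Extra identifying columns (e.g. `dataset`, `method`),
#'   recycled across rows.
#' @return data.frame with one row per metric (`metric`, `value`, ...).
#' @export
metrics_as_table <- function(x, ...) {
  stopifnot(inherits(x, "metrics_report"))
  ms <- c("ari", "nmi", "asw_celltype", "isolated_f1", "silhouette")
  data.frame(..., metric = ms, value = vapply(ms, function(m) x[[m]],
                                              numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
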