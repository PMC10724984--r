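#' KNN label transfer in the latent space
#'
#' Predicts a label for every query cell from the majority label among its
#' `k` Euclidean nearest reference cells.  Count ties are broken by the
#' smaller summed distance of the tied label's neighbors, remaining ties
#' lexicographically by label.
#'
#' @param reference_embedding Matrix, reference cells x dimensions.
#' @param reference_labels Per-reference-cell labels.
#' @param query_embedding Matrix, query cells x the same dimensions.
#' @param k Number of neighbors (default 15).
#' @return Character vector of predicted labels, one per query cell.
#' @export
knn_transfer <- function(reference_embedding, reference_labels,
                         query_embedding, k = 15) {
  ref <- as.matrix(reference_embedding)
  qry <- as.matrix(query_embedding)
  labs <- as.character(reference_labels)
  if (nrow(ref) == 0) stop("reference embedding is empty")
  if (nrow(ref) != length(labs))
    stop("need one label per reference cell")
  if (ncol(ref) != ncol(qry))
    stop("reference and query embeddings differ in dimension (",
         ncol(ref), " vs ", ncol(qry), ")")
  if (k < 1 || k > nrow(ref))
    stop("k must lie in 1..", nrow(ref), " (reference size); got ", k)

  # squared Euclidean distances query x reference
  d2 <- outer(rowSums(qry^2), rowSums(ref^2), "+") - 2 * tcrossprod(qry, ref)
  d2[d2 < 0] <- 0
  pred <- character(nrow(qry))
  for (i in seq_len(nrow(qry))) {
    nn <- order(d2[i, ], seq_len(ncol(d2)))[seq_len(k)]
    nn_lab <- labs[nn]
    counts <- table(nn_lab)
    top <- names(counts)[counts == max(counts)]
    if (length(top) > 1) {
      sums <- vapply(top, function(l) sum(sqrt(d2[i, nn[nn_lab == l]])),
                     numeric(1))
      top <- top[sums == min(sums)]
      top <- sort(top)[1]
    }
    pred[i] <- top
  }
  pred
}

#' Confusion matrix of predicted vs true labels
#'
#' @param true_labels,predicted_labels Per-cell labels of equal length.
#' @return Object of class `confusion_matrix`: integer matrix with rows =
#'   true types, columns = predicted types, both sorted lexicographically
#'   over the union of observed labels.  Row sums equal per-class counts.
#' @export
confusion <- function(true_labels, predicted_labels) {
  tl <- as.character(true_labels)
  pl <- as.character(predicted_labels)
  if (length(tl) != length(pl)) stop("label vectors differ in length")
  levs <- sort(unique(c(tl, pl)))
  cm <- table(factor(tl, levels = levs), factor(pl, levels = levs))
  cm <- matrix(as.integer(cm), nrow = length(levs),
               dimnames = list(true = levs, predicted = levs))
  structure(cm, class = c("confusion_matrix", class(cm)))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> (rows: true, columns: predicted)\n")
  print(unclass(x))
  invisible(x)
}

#' Per-class recall from a confusion matrix
#'
#' @param cm A [confusion()] result.
#' @return Named numeric vector (diagonal / row sums; NA for empty classes).
#' @export
class_recall <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  rs <- rowSums(cm)
  ifelse(rs > 0, diag(cm) / rs, NA_real_)
}

#' Write a confusion matrix as a labeled delimited table
#'
#' @param cm A [confusion()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_confusion <- function(cm, path) {
  df <- data.frame(true = rownames(cm), unclass(cm), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
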