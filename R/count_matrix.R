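#' Cells-by-genes expression container
#'
#' Lightweight container for a cells x genes expression matrix together
#' with per-cell batch (and optionally cell-type) labels.  `values` holds
#' the current working layer (raw counts before normalization, normalized
#' and/or log-transformed values afterwards); `raw` keeps the integer count
#' layer once normalization has replaced the working layer, so operations
#' such as binomial count downsampling can act on integers.
#'
#' @param values A base matrix or `Matrix` sparse matrix, cells in rows,
#'   genes in columns.  Row/column names are used as cell ids and gene
#'   symbols; defaults are generated when absent.
#' @param batch Per-cell batch labels (length = number of cells); coerced
#'   to factor.
#' @param celltype Optional per-cell cell-type labels; coerced to factor.
#' @param raw Optional raw-count layer with the same dimensions.
#' @return Object of class `count_matrix` with fields `values`, `raw`,
#'   `batch`, `celltype`.
#' @export
count_matrix <- function(values, batch, celltype = NULL, raw = NULL) {
  if (!(is.matrix(values) || inherits(values, "Matrix")))
    stop("values must be a matrix or Matrix")
  if (min(values) < 0) stop("expression values must be nonnegative")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("cell_%d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("gene_%d", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values))) stop("cell ids must be unique")
  if (anyDuplicated(colnames(values))) stop("gene symbols must be unique")
  if (length(batch) != nrow(values))
    stop("batch labels must have one entry per cell (",
         nrow(values), " cells, ", length(batch), " labels)")
  if (!is.null(celltype) && length(celltype) != nrow(values))
    stop("celltype labels must have one entry per cell")
  if (!is.null(raw) && !all(dim(raw) == dim(values)))
    stop("raw layer dimensions must match values")
  structure(
    list(values = values,
         raw = raw,
         batch = factor(batch),
         celltype = if (is.null(celltype)) NULL else factor(celltype)),
    class = "count_matrix"
  )
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' @export
print.count_matrix <- function(x, ...) {
  cat("<count_matrix> ", nrow(x$values), " cells x ", ncol(x$values),
      " genes; ", nlevels(x$batch), " batch(es)",
      if (!is.null(x$celltype)) paste0("; ", nlevels(x$celltype), " cell type(s)"),
      if (!is.null(x$raw)) "; raw layer retained",
      "\n", sep = "")
  invisible(x)
}

#' Cell ids and gene symbols
#' @param x A `count_matrix`.
#' @return Character vector.
#' @export
cell_ids <- function(x) rownames(x$values)

#' @rdname cell_ids
#' @export
gene_symbols <- function(x) colnames(x$values)

# Subset cells (rows), keeping labels and layers consistent.
subset_cells <- function(x, idx) {
  count_matrix(
    x$values[idx, , drop = FALSE],
    batch = as.character(x$batch)[idx],
    celltype = if (is.null(x$celltype)) NULL else as.character(x$celltype)[idx],
    raw = if (is.null(x$raw)) NULL else x$raw[idx, , drop = FALSE]
  )
}

# Subset genes (columns).
subset_genes <- function(x, idx) {
  count_matrix(
    x$values[, idx, drop = FALSE],
    batch = as.character(x$batch),
    celltype = if (is.null(x$celltype)) NULL else as.character(x$celltype),
    raw = if (is.null(x$raw)) NULL else x$raw[, idx, drop = FALSE]
  )
}

# Dense numeric copy of the working layer.
dense_values <- function(x) {
  v <- x$values
  if (inherits(v, "Matrix")) as.matrix(v) else v
}
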