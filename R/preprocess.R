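#' Filter cells by number of expressed genes
#'
#' Keeps exactly the cells expressing (count > 0) at least `min_genes`
#' genes.  The threshold is inclusive and the original cell order is
#' preserved; batch/cell-type labels are subset consistently.
#'
#' @param x A [count_matrix()] holding raw counts.
#' @param min_genes Minimum number of expressed genes per cell (default
#'   600, the standard atlas preprocessing threshold).
#' @return Filtered `count_matrix`.
#' @export
filter_cells <- function(x, min_genes = 600) {
  stopifnot(inherits(x, "count_matrix"))
  n_expressed <- Matrix::rowSums(x$values > 0)
  keep <- n_expressed >= min_genes
  if (!any(keep))
    stop("filter_cells removed every cell (min_genes = ", min_genes,
         "; observed per-cell expressed-gene range ",
         min(n_expressed), "-", max(n_expressed), ")")
  subset_cells(x, which(keep))
}

#' Filter genes by number of expressing cells
#'
#' Keeps genes expressed (count > 0) in at least `min_cells` cells
#' (inclusive); gene order preserved.
#'
#' @param x A [count_matrix()].
#' @param min_cells Minimum number of cells (default 3).
#' @return Filtered `count_matrix`.
#' @export
filter_genes <- function(x, min_cells = 3) {
  stopifnot(inherits(x, "count_matrix"))
  n_cells <- Matrix::colSums(x$values > 0)
  keep <- n_cells >= min_cells
  if (!any(keep))
    stop("filter_genes removed every gene (min_cells = ", min_cells, ")")
  subset_genes(x, which(keep))
}

#' Median-count normalization
#'
#' Rescales every cell so its total equals the median of the per-cell
#' totals of the input (the default target of total-count normalization in
#' standard scRNA-seq toolchains).  The pre-normalization layer is kept as
#' `raw` so downstream integer-count operations remain possible.
#'
#' @param x A filtered [count_matrix()]; no cell may have total 0.
#' @return `count_matrix` with normalized `values` and the input layer in
#'   `raw`.
#' @export
normalize_total <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  totals <- Matrix::rowSums(x$values)
  if (any(totals == 0))
    stop("cell(s) with zero total count: ",
         paste(utils::head(rownames(x$values)[totals == 0], 5), collapse = ", "),
         "; filter cells first")
  target <- stats::median(totals)
  scaled <- x$values * (target / totals)  # row-wise recycling over columns
  count_matrix(scaled,
               batch = as.character(x$batch),
               celltype = if (is.null(x$celltype)) NULL else as.character(x$celltype),
               raw = if (is.null(x$raw)) x$values else x$raw)
}

#' Log-transform expression values
#'
#' Elementwise natural log(1 + v); zero-preserving and monotone.
#'
#' @param x A [count_matrix()].
#' @return `count_matrix` with log-transformed `values`.
#' @export
log1p_counts <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  x$values <- log1p(x$values)
  x
}

#' Select highly variable genes
#'
#' Dispersion-based HVG selection on normalized, log-transformed data:
#' per-gene mean and dispersion (variance/mean) are computed on
#' `expm1(values)`, genes are grouped into `n_bins` equal-frequency bins by
#' mean, the dispersion is z-scored within each bin, and the `n_top` genes
#' with the largest normalized dispersion are flagged.  Ties are broken by
#' input gene order.  Genes with undefined dispersion (zero mean or zero
#' variance) are never flagged.
#'
#' @param x A normalized + log-transformed [count_matrix()].
#' @param n_top Number of genes to flag (default 2000).
#' @param n_bins Number of mean-expression bins (default 20).
#' @return A data.frame (`hvg_report`) with one row per gene: `gene`,
#'   `mean`, `dispersion`, `dispersion_norm`, `highly_variable`.
#' @export
select_hvg <- function(x, n_top = 2000, n_bins = 20) {
  stopifnot(inherits(x, "count_matrix"))
  if (n_top < 1) stop("n_top must be a positive integer")
  if (n_bins < 1) stop("n_bins must be a positive integer")
  m <- expm1(dense_values(x))
  n <- nrow(m)
  mu <- colMeans(m)
  v <- if (n > 1) (colMeans(m^2) - mu^2) * n / (n - 1) else rep(0, ncol(m))
  disp <- ifelse(mu > 0, v / mu, NA_real_)
  disp[!is.finite(disp) | disp <= 0] <- NA_real_

  nd <- rep(NA_real_, length(disp))
  ok <- !is.na(disp)
  if (any(ok)) {
    breaks <- unique(stats::quantile(mu[ok], probs = seq(0, 1, length.out = n_bins + 1)))
    bin <- if (length(breaks) > 1) {
      cut(mu[ok], breaks = breaks, include.lowest = TRUE)
    } else factor(rep(1, sum(ok)))
    z <- stats::ave(disp[ok], bin, FUN = function(d) {
      s <- stats::sd(d)
      if (!is.finite(s) || s == 0) rep(0, length(d)) else (d - mean(d)) / s
    })
    nd[ok] <- z
  }

  n_avail <- sum(ok)
  n_flag <- min(n_top, n_avail)
  if (n_avail < n_top)
    warning("only ", n_avail, " genes have finite dispersion; flagging all of them")
  flagged <- rep(FALSE, length(disp))
  if (n_flag > 0) {
    key <- nd
    key[is.na(key)] <- -Inf
    ord <- order(-key, seq_along(key))  # stable: earlier gene wins ties
    flagged[ord[seq_len(n_flag)]] <- TRUE
  }
  structure(
    data.frame(gene = gene_symbols(x), mean = mu, dispersion = disp,
               dispersion_norm = nd, highly_variable = flagged,
               row.names = NULL, stringsAsFactors = FALSE),
    class = c("hvg_report", "data.frame")
  )
}

#' Run the full preprocessing pipeline
#'
#' Applies, in order: [filter_cells()], [filter_genes()],
#' [normalize_total()], [log1p_counts()], [select_hvg()], and restriction
#' to the flagged genes.  A provenance record (dimensions before/after
#' every step plus the parameters used) is attached as attribute
#' `"provenance"`, and the HVG report as attribute `"hvg"`.
#'
#' @param x A raw-count [count_matrix()].
#' @param min_genes,min_cells,n_top,n_bins Step parameters; see the
#'   individual functions.
#' @return Preprocessed `count_matrix` restricted to highly variable
#'   genes, log-normalized `values` and integer `raw` layer.
#' @export
run_pipeline <- function(x, min_genes = 600, min_cells = 3,
                         n_top = 2000, n_bins = 20) {
  stopifnot(inherits(x, "count_matrix"))
  steps <- list(input = dim(x))
  x <- filter_cells(x, min_genes = min_genes); steps$filter_cells <- dim(x)
  x <- filter_genes(x, min_cells = min_cells); steps$filter_genes <- dim(x)
  x <- normalize_total(x);                     steps$normalize_total <- dim(x)
  x <- log1p_counts(x)
  hvg <- select_hvg(x, n_top = n_top, n_bins = n_bins)
  x <- subset_genes(x, which(hvg$highly_variable))
  steps$select_hvg <- dim(x)
  attr(x, "hvg") <- hvg
  attr(x, "provenance") <- list(
    steps = steps,
    params = list(min_genes = min_genes, min_cells = min_cells,
                  n_top = n_top, n_bins = n_bins),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  x
}

#' Write a provenance record as key-value text
#'
#' @param x Output of [run_pipeline()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(x, path) {
  pr <- attr(x, "provenance")
  if (is.null(pr)) stop("object carries no provenance record")
  lines <- c(
    vapply(names(pr$steps), function(s)
      sprintf("dim.%s=%dx%d", s, pr$steps[[s]][1], pr$steps[[s]][2]), character(1)),
    vapply(names(pr$params), function(p)
      sprintf("param.%s=%s", p, format(pr$params[[p]])), character(1)),
    sprintf("timestamp=%s", pr$timestamp)
  )
  writeLines(lines, path)
  invisible(path)
}
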