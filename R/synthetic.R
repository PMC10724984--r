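#' Ground truth for the multi-batch count simulator
#'
#' Draws a reproducible ground-truth configuration: a binary pathway-gene
#' adjacency `A_true` (pathways own blocks of `genes_per_pathway` genes,
#' disjoint when `P * genes_per_pathway <= G`, randomly overlapping
#' otherwise), per-cell-type sparse pathway programs (each type activates
#' `active_per_type` pathways with log-scale strengths drawn uniformly
#' from `program_range`), a per-gene log baseline, and multiplicative
#' log-normal per-batch per-gene factors that mimic platform bias.
#'
#' @param P Number of pathways (default 10).
#' @param G Number of genes (default 200).
#' @param T_types Number of cell types (default 4).
#' @param B Number of batches (default 2).
#' @param genes_per_pathway Genes in each pathway (default 20).
#' @param active_per_type Pathways active per cell type (default 3).
#' @param program_range Range of per-pathway activity strengths on the
#'   log scale (default `c(1, 2)`).
#' @param baseline_log_mean,baseline_log_sd Per-gene baseline log-mean
#'   distribution (default `log(2)`, 0.8).
#' @param batch_sigma SD of the log-normal batch factors (default 0.5,
#'   a clearly visible technical effect).
#' @param dispersion Negative-binomial size parameter shared by all genes
#'   (default 2; variance = mu + mu^2 / dispersion).
#' @param seed Integer seed.
#' @return Object of class `synthetic_truth` with fields `A_true`,
#'   `type_programs`, `gene_baseline`, `batch_factors`, `dispersion`,
#'   `seed` and the dimensions.
#' @export
make_truth <- function(P = 10, G = 200, T_types = 4, B = 2,
                       genes_per_pathway = 20, active_per_type = 3,
                       program_range = c(1, 2),
                       baseline_log_mean = log(2), baseline_log_sd = 0.8,
                       batch_sigma = 0.5, dispersion = 2, seed = 1) {
  stopifnot(P >= 1, G >= 1, T_types >= 1, B >= 1,
            genes_per_pathway >= 1, genes_per_pathway <= G,
            active_per_type >= 1, dispersion > 0)
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(G))
  pathways <- sprintf("PATHWAY_%02d", seq_len(P))

  A <- matrix(0, P, G, dimnames = list(pathways, genes))
  if (P * genes_per_pathway <= G) {
    perm <- sample.int(G)
    for (p in seq_len(P)) {
      block <- perm[((p - 1) * genes_per_pathway + 1):(p * genes_per_pathway)]
      A[p, block] <- 1
    }
  } else {
    for (p in seq_len(P)) A[p, sample.int(G, genes_per_pathway)] <- 1
  }

  progs <- matrix(0, T_types, P,
                  dimnames = list(sprintf("type_%d", seq_len(T_types)),
                                  pathways))
  npick <- min(active_per_type, P)
  for (t in seq_len(T_types)) {
    on <- sample.int(P, npick)
    progs[t, on] <- stats::runif(npick, program_range[1], program_range[2])
  }

  structure(
    list(A_true = A,
         type_programs = progs,
         gene_baseline = stats::rnorm(G, baseline_log_mean, baseline_log_sd),
         batch_factors = matrix(exp(stats::rnorm(B * G, 0, batch_sigma)),
                                B, G,
                                dimnames = list(sprintf("batch_%d", seq_len(B)),
                                                genes)),
         dispersion = dispersion, seed = seed,
         P = P, G = G, T_types = T_types, B = B),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth> ", x$P, " pathways, ", x$G, " genes, ",
      x$T_types, " types, ", x$B, " batches (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Simulate multi-batch negative-binomial counts
#'
#' Per cell of type t in batch b, gene means are
#' `exp(baseline + program(t) %*% A_true) * batch_factor(b)` and counts
#' are drawn negative-binomially with the truth's shared dispersion, so
#' cell identity lives in pathway programs and batches differ only by
#' technical multiplicative factors.
#'
#' @param truth A [make_truth()] result.
#' @param n_cells_per_type_per_batch Cells simulated for every
#'   (type, batch) pair (default 50).
#' @param seed Integer seed (independent of the truth's seed).
#' @return A [count_matrix()] with integer counts, `batch` and `celltype`
#'   labels.
#' @export
simulate_counts <- function(truth, n_cells_per_type_per_batch = 50,
                            seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"),
            n_cells_per_type_per_batch >= 1)
  set.seed(seed)
  n_per <- n_cells_per_type_per_batch
  type_names <- rownames(truth$type_programs)
  batch_names <- rownames(truth$batch_factors)
  # log-mean per type (before batch factor)
  type_logmu <- sweep(truth$type_programs %*% truth$A_true, 2,
                      truth$gene_baseline, "+")
  cells_ct <- rep(rep(type_names, each = n_per), times = truth$B)
  cells_ba <- rep(batch_names, each = n_per * truth$T_types)
  n_cells <- length(cells_ct)
  mu <- exp(type_logmu[cells_ct, , drop = FALSE]) *
    truth$batch_factors[cells_ba, , drop = FALSE]
  counts <- matrix(stats::rnbinom(n_cells * truth$G, mu = as.vector(mu),
                                  size = truth$dispersion),
                   n_cells, truth$G)
  dimnames(counts) <- list(sprintf("%s_%s_%04d", cells_ba, cells_ct,
                                   seq_len(n_cells)),
                           colnames(truth$A_true))
  count_matrix(counts, batch = cells_ba, celltype = cells_ct)
}

# Integer count layer an operation should act on (raw if present).
raw_counts_layer <- function(x) {
  v <- if (!is.null(x$raw)) x$raw else x$values
  vd <- if (inherits(v, "Matrix")) as.matrix(v) else v
  if (any(vd != round(vd)))
    stop("operation requires integer counts (raw layer missing or non-integer)")
  vd
}

#' Binomial count downsampling
#'
#' Randomly loses counts: every unit of every raw count survives
#' independently with probability `keep_fraction` (binomial thinning), so
#' the expected total equals `keep_fraction` times the input total.  This
#' emulates the loss of sequencing depth in which potential marker-gene
#' expression disappears.
#'
#' @param x A [count_matrix()] with integer counts (raw layer used when
#'   present).
#' @param keep_fraction Probability in `[0, 1]` that a count unit survives.
#' @param seed Integer seed.
#' @return A fresh `count_matrix` of thinned integer counts with the same
#'   labels.
#' @export
downsample_counts <- function(x, keep_fraction, seed = 1) {
  stopifnot(inherits(x, "count_matrix"),
            keep_fraction >= 0, keep_fraction <= 1)
  v <- raw_counts_layer(x)
  set.seed(seed)
  thinned <- matrix(stats::rbinom(length(v), size = as.vector(v),
                                  prob = keep_fraction),
                    nrow(v), ncol(v), dimnames = dimnames(v))
  count_matrix(thinned, batch = as.character(x$batch),
               celltype = if (is.null(x$celltype)) NULL
                          else as.character(x$celltype))
}

#' Random cell subsampling
#'
#' Samples cells without replacement, keeping `keep_fraction` of them
#' (optionally stratified so per-group proportions are preserved to
#' rounding).  Labels are subset consistently and the original cell order
#' is preserved.
#'
#' @param x A [count_matrix()].
#' @param keep_fraction Fraction of cells to keep in `[0, 1]`.
#' @param seed Integer seed.
#' @param stratify_by Optional per-cell labels (or `"celltype"` /
#'   `"batch"` to use the stored labels) to stratify over.
#' @return Subsampled `count_matrix`.
#' @export
subsample_cells <- function(x, keep_fraction, seed = 1, stratify_by = NULL) {
  stopifnot(inherits(x, "count_matrix"),
            keep_fraction >= 0, keep_fraction <= 1)
  n <- nrow(x$values)
  set.seed(seed)
  if (is.null(stratify_by)) {
    keep <- sort(sample.int(n, round(keep_fraction * n)))
  } else {
    strata <- if (identical(stratify_by, "celltype")) x$celltype
              else if (identical(stratify_by, "batch")) x$batch
              else stratify_by
    if (length(strata) != n) stop("stratify_by must have one entry per cell")
    keep <- sort(unlist(lapply(split(seq_len(n), strata), function(idx) {
      sample(idx, round(keep_fraction * length(idx)))
    }), use.names = FALSE))
  }
  if (length(keep) == 0) stop("subsampling removed every cell")
  subset_cells(x, keep)
}

#' Hold out cell types per batch
#'
#' Removes every cell whose (batch, cell type) pair appears in the plan,
#' emulating batches that each lack one population, so integration must
#' preserve dataset-specific types.
#'
#' @param x A [count_matrix()] with cell-type labels.
#' @param plan Named list: names are batch labels, values are character
#'   vectors of cell types to drop from that batch.
#' @return Filtered `count_matrix`.
#' @export
holdout_cell_types <- function(x, plan) {
  stopifnot(inherits(x, "count_matrix"))
  if (length(plan) == 0) return(x)
  if (is.null(x$celltype)) stop("cell-type labels are required")
  unknown <- setdiff(names(plan), levels(x$batch))
  if (length(unknown) > 0)
    stop("plan references unknown batch(es): ",
         paste(unknown, collapse = ", "))
  drop <- rep(FALSE, nrow(x$values))
  for (b in names(plan))
    drop <- drop | (as.character(x$batch) == b &
                    as.character(x$celltype) %in% plan[[b]])
  if (all(drop)) stop("holdout plan removed every cell")
  subset_cells(x, which(!drop))
}

#' Write a complete synthetic fixture to disk
#'
#' Emits a self-contained input set for the full pipeline: the counts as
#' Matrix Market (`matrix.mtx`, cells x genes), cell metadata
#' (`cells.tsv`: id, batch, cell type), gene symbols (`genes.tsv`), the
#' ground-truth pathways as a GMT file (`pathways.gmt`, built from
#' `A_true` verbatim so parameter recovery has an exact reference), and a
#' key-value `manifest.txt` recording the generator parameters.
#'
#' @param truth A [make_truth()] result.
#' @param x The [count_matrix()] simulated from it.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(truth, x, dir) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(x, "count_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(raw_counts_layer(x), sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  utils::write.table(
    data.frame(cell_id = cell_ids(x), batch = as.character(x$batch),
               celltype = if (is.null(x$celltype)) NA
                          else as.character(x$celltype)),
    file.path(dir, "cells.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene = gene_symbols(x)),
                     file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sets <- lapply(rownames(truth$A_true), function(p) {
    gene_set(p, "synthetic", colnames(truth$A_true)[truth$A_true[p, ] != 0])
  })
  write_gmt(sets, file.path(dir, "pathways.gmt"))
  writeLines(c(sprintf("P=%d", truth$P), sprintf("G=%d", truth$G),
               sprintf("T=%d", truth$T_types), sprintf("B=%d", truth$B),
               sprintf("dispersion=%g", truth$dispersion),
               sprintf("seed=%d", truth$seed)),
             file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' Read a fixture directory back
#'
#' Inverse of [write_fixture()] (and a general reader for MTX + TSV
#' sidecar inputs).
#'
#' @param dir Directory containing `matrix.mtx`, `cells.tsv`, `genes.tsv`
#'   and optionally `pathways.gmt`.
#' @return List with `X` (a [count_matrix()]) and `gene_sets` (list of
#'   [gene_set], or NULL when no GMT file is present).
#' @export
read_fixture <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) stop("no matrix.mtx in ", dir)
  m <- as.matrix(Matrix::readMM(mtx))
  cells <- utils::read.delim(file.path(dir, "cells.tsv"),
                             stringsAsFactors = FALSE)
  genes <- utils::read.delim(file.path(dir, "genes.tsv"),
                             stringsAsFactors = FALSE)
  dimnames(m) <- list(cells$cell_id, genes$gene)
  ct <- if ("celltype" %in% names(cells) && !all(is.na(cells$celltype)))
    cells$celltype else NULL
  gmt <- file.path(dir, "pathways.gmt")
  list(X = count_matrix(m, batch = cells$batch, celltype = ct),
       gene_sets = if (file.exists(gmt)) parse_gmt(gmt) else NULL)
}
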