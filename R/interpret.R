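#' Per-cell pathway activity table
#'
#' The latent embedding with pathway names attached: each column is the
#' posterior-mean activity of one pathway in each cell, identical in value
#' to [transform_cells()].  Cell-type labels are carried through for
#' downstream plotting/grouping.
#'
#' @param model A fitted `pathvae_model`.
#' @param X A [count_matrix()] of log-normalized values.
#' @param batch Optional batch override (defaults to `X$batch`).
#' @return Object of class `pathway_activity`: list with `values`
#'   (cells x P matrix, pathway colnames), `cell_ids`, `celltype`.
#' @export
pathway_activity <- function(model, X, batch = NULL) {
  emb <- transform_cells(model, X, batch = batch)
  structure(
    list(values = emb,
         cell_ids = rownames(emb),
         celltype = if (inherits(X, "count_matrix")) X$celltype else NULL),
    class = "pathway_activity"
  )
}

#' @export
print.pathway_activity <- function(x, ...) {
  cat("<pathway_activity> ", nrow(x$values), " cells x ", ncol(x$values),
      " pathways\n", sep = "")
  invisible(x)
}

#' Select pathways by name pattern
#'
#' Keeps the columns whose pathway names contain any of the given
#' patterns (case-insensitive substring match), preserving column order.
#' The reduced table is itself a valid embedding, e.g. for
#' [evaluate_all()] — this is how a themed subset of pathways (say, all
#' immune-related ones) can be used as the cell representation.
#'
#' @param table A [pathway_activity()] result.
#' @param patterns Non-empty character vector of substrings.
#' @return A `pathway_activity` restricted to the matching columns.
#' @export
select_pathways <- function(table, patterns) {
  stopifnot(inherits(table, "pathway_activity"))
  if (length(patterns) == 0 || all(!nzchar(patterns)))
    stop("patterns must be a non-empty list of non-empty strings")
  nms <- colnames(table$values)
  hit <- rep(FALSE, length(nms))
  for (p in patterns)
    hit <- hit | grepl(p, nms, ignore.case = TRUE, fixed = FALSE)
  if (!any(hit))
    stop("no pathway name matches ", paste(patterns, collapse = ", "),
         "; available: ", paste(nms, collapse = ", "))
  table$values <- table$values[, hit, drop = FALSE]
  table
}

#' Rank genes by decoder weight for one pathway
#'
#' Sorts genes by their decoder weight in the chosen pathway row, either
#' by signed value (`mode = "signed"`) or by magnitude
#' (`mode = "absolute"`).  Each returned gene carries an `in_prior` flag
#' marking whether the adjacency links it to the pathway, which exposes
#' candidate pathway members the prior did not contain.
#'
#' @param model A fitted `pathvae_model` (its decoder weights and
#'   adjacency are used), or a bare P x G weight matrix plus `A`.
#' @param pathway Pathway name.
#' @param top_k Number of genes to return (default 20; capped at G).
#' @param mode `"signed"` or `"absolute"`.
#' @param A Optional `pathway_matrix` when `model` is a bare matrix.
#' @return Object of class `gene_ranking`: data.frame with `rank`, `gene`,
#'   `weight`, `in_prior`, plus attributes `pathway` and `mode`.  Ties keep
#'   input gene order.
#' @export
rank_genes_for_pathway <- function(model, pathway, top_k = 20,
                                   mode = c("signed", "absolute"), A = NULL) {
  mode <- match.arg(mode)
  if (top_k < 1) stop("top_k must be positive")
  if (inherits(model, "pathvae_model")) {
    w <- decoder_weights(model)
    Amat <- model$adjacency
  } else {
    w <- model
    if (is.null(A)) stop("supply A when model is a bare weight matrix")
    Amat <- if (inherits(A, "pathway_matrix")) A$A else A
    dimnames(w) <- dimnames(Amat)
  }
  if (!pathway %in% rownames(w))
    stop("unknown pathway '", pathway, "'; available: ",
         paste(utils::head(rownames(w), 20), collapse = ", "))
  wp <- w[pathway, ]
  key <- if (mode == "absolute") abs(wp) else wp
  ord <- order(-key, seq_along(key))
  top_k <- min(top_k, length(wp))
  sel <- ord[seq_len(top_k)]
  structure(
    data.frame(rank = seq_len(top_k),
               gene = colnames(w)[sel],
               weight = unname(wp[sel]),
               in_prior = unname(Amat[pathway, sel] != 0),
               stringsAsFactors = FALSE),
    pathway = pathway, mode = mode,
    class = c("gene_ranking", "data.frame")
  )
}

#' Write gene rankings for all pathways of a model
#'
#' One delimited table with columns `pathway`, `rank`, `gene`, `weight`,
#' `in_prior` — the shape of a supplementary gene-list table.
#'
#' @param model A fitted `pathvae_model`.
#' @param path Output TSV path.
#' @param top_k Genes per pathway.
#' @param mode `"signed"` or `"absolute"`.
#' @return `path`, invisibly.
#' @export
write_gene_rankings <- function(model, path, top_k = 20,
                                mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  tabs <- lapply(model$pathways, function(p) {
    r <- rank_genes_for_pathway(model, p, top_k = top_k, mode = mode)
    cbind(pathway = p, as.data.frame(r))
  })
  utils::write.table(do.call(rbind, tabs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
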