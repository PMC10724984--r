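#' Gene set
#'
#' A named collection of gene symbols, typically one line of a GMT file.
#' Symbols are canonicalized to upper case and de-duplicated (first
#' occurrence wins), so matching against an expression gene universe is
#' case-insensitive.
#'
#' @param name Non-empty character scalar identifying the set (pathway).
#' @param description Free-text description (may be empty).
#' @param genes Character vector of gene symbols; must be non-empty after
#'   canonicalization.
#' @return An object of class `gene_set` with fields `name`, `description`
#'   and `genes`.
#' @export
gene_set <- function(name, description = "", genes = character()) {
  name <- as.character(name)
  if (length(name) != 1L || !nzchar(name))
    stop("gene set name must be a non-empty string")
  genes <- toupper(as.character(genes))
  genes <- genes[nzchar(genes)]
  genes <- genes[!duplicated(genes)]
  if (length(genes) == 0L)
    stop("gene set '", name, "' has no genes")
  structure(
    list(name = name, description = as.character(description)[1L], genes = genes),
    class = "gene_set"
  )
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set> ", x$name, ": ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Parse a GMT gene-set file
#'
#' Reads the MSigDB/WikiPathways GMT dialect: one gene set per line,
#' tab-separated fields `name`, `description`, then gene symbols.  Trailing
#' empty fields are tolerated; blank lines are skipped.  Gene symbols are
#' upper-cased and duplicates within a line are collapsed, preserving order.
#'
#' @param path Path to a GMT file.
#' @return A list of [gene_set] objects, in file order.  An empty file
#'   yields an empty list.
#' @examples
#' f <- tempfile(fileext = ".gmt")
#' writeLines("PW1\tdesc\tGENEA\tgeneb\tGENEA", f)
#' parse_gmt(f)[[1]]$genes  # "GENEA" "GENEB"
#' @export
parse_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  out <- vector("list", length(lines))
  j <- 0L
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[i]))) next
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    while (length(fields) > 0L && !nzchar(fields[length(fields)]))
      fields <- fields[-length(fields)]
    if (length(fields) < 3L)
      stop("malformed GMT line ", i, " in '", path,
           "': expected at least 3 tab-separated fields (name, description, genes...)")
    j <- j + 1L
    out[[j]] <- gene_set(fields[1L], fields[2L], fields[-(1:2)])
  }
  out[seq_len(j)]
}

#' Write gene sets to a GMT file
#'
#' Emits the same tab-separated dialect accepted by [parse_gmt()].
#'
#' @param gene_sets List of [gene_set] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(gene_sets, function(gs) {
    paste(c(gs$name, gs$description, gs$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Build a pathway-gene adjacency matrix
#'
#' Constructs the binary prior matrix used to regularize the decoder: entry
#' `[p, g]` is 1 iff gene `g` of the expression gene universe belongs to
#' pathway `p`.  Columns follow the supplied universe order exactly, so the
#' matrix aligns with the expression matrix by construction.  Pathways
#' overlapping the universe in fewer than `min_overlap` genes are dropped;
#' the number of surviving pathways defines the latent dimension of the
#' model.  Genes belonging to no pathway keep all-zero columns (they are
#' still reconstructed by the decoder).
#'
#' @param gene_sets List of [gene_set] objects (e.g. from [parse_gmt()]).
#' @param gene_universe Character vector of gene symbols (the expression
#'   matrix gene order); canonicalized to upper case, must be unique.
#' @param min_overlap Minimum number of universe genes a pathway must
#'   contain to be kept (inclusive).  Default 5 avoids latent dimensions
#'   driven by one or two genes.
#' @return An object of class `pathway_matrix`: list with `A` (P x G binary
#'   matrix, dimnames pathway x gene), `pathways`, `genes`.
#' @export
build_adjacency <- function(gene_sets, gene_universe, min_overlap = 5) {
  if (length(gene_universe) == 0L) stop("gene universe is empty")
  universe <- toupper(as.character(gene_universe))
  if (anyDuplicated(universe))
    stop("gene universe contains duplicate symbols after canonicalization")
  if (min_overlap < 1) stop("min_overlap must be a positive integer")
  if (length(gene_sets) == 0L)
    stop("no gene sets supplied")

  P0 <- length(gene_sets)
  A <- matrix(0, nrow = P0, ncol = length(universe),
              dimnames = list(vapply(gene_sets, `[[`, character(1), "name"),
                              universe))
  for (p in seq_len(P0)) {
    A[p, universe %in% gene_sets[[p]]$genes] <- 1
  }
  keep <- rowSums(A) >= min_overlap
  if (!any(keep))
    stop("no pathway overlaps the gene universe in at least ", min_overlap,
         " genes; use a different knowledge database or lower min_overlap")
  A <- A[keep, , drop = FALSE]
  if (anyDuplicated(rownames(A)))
    stop("duplicate pathway names among surviving gene sets: ",
         paste(unique(rownames(A)[duplicated(rownames(A))]), collapse = ", "))
  structure(
    list(A = A, pathways = rownames(A), genes = universe),
    class = "pathway_matrix"
  )
}

#' @export
print.pathway_matrix <- function(x, ...) {
  cat("<pathway_matrix> ", nrow(x$A), " pathways x ", ncol(x$A), " genes, ",
      sum(x$A), " links\n", sep = "")
  invisible(x)
}

#' Convert a pathway matrix back to gene sets
#'
#' Inverse of [build_adjacency()] restricted to the gene universe: each row
#' becomes a [gene_set] containing the member genes in universe order.
#'
#' @param pm A `pathway_matrix`.
#' @return List of [gene_set] objects.
#' @export
adjacency_to_gene_sets <- function(pm) {
  stopifnot(inherits(pm, "pathway_matrix"))
  lapply(seq_len(nrow(pm$A)), function(p) {
    gene_set(pm$pathways[p], "", pm$genes[pm$A[p, ] != 0])
  })
}
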