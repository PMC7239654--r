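#' Genes significant in at least one screen
#'
#' Union of genes passing the (strict) FDR threshold in any screen, ordered by
#' their best q-value across screens, ties broken by gene id. This is the gene
#' set carried into the cross-screen IGTIOB comparison; the threshold is
#' deliberately relaxed relative to top-hit calling so that hits unique to one
#' screen are not missed.
#'
#' @param results_list list of tibbles from [screen_enrichment()].
#' @param alpha FDR threshold in (0, 1]; genes require `q < alpha` (strict).
#' @return Character vector of gene ids (possibly empty, with a warning).
#' @export
union_significant <- function(results_list, alpha = 0.01) {
  if (length(results_list) < 1) abort("need at least one result table")
  if (alpha <= 0 || alpha > 1) abort("alpha must be in (0, 1]")
  all_res <- dplyr::bind_rows(results_list)
  sig <- all_res[!is.na(all_res$q) & all_res$q < alpha, ]
  if (nrow(sig) == 0) {
    warn("no gene passes the significance threshold in any screen")
    return(character(0))
  }
  best <- dplyr::summarise(dplyr::group_by(all_res, .data$gene_id),
                           min_q = min(.data$q), .groups = "drop")
  best <- best[best$gene_id %in% unique(sig$gene_id), ]
  best <- best[order(best$min_q, best$gene_id, method = "radix"), ]
  best$gene_id
}

#' Hierarchical leaf ordering of a gene score matrix
#'
#' Agglomerative clustering (Euclidean distance, average linkage) of the rows
#' of a genes x screens score matrix, returning the dendrogram leaf order.
#' Rows are pre-sorted by gene id so the result is invariant under input row
#' permutation; missing scores must be imputed by the caller.
#'
#' @param mat numeric matrix with gene ids as rownames, one column per screen.
#' @return Character vector of gene ids in leaf order.
#' @export
cluster_rows <- function(mat) {
  if (is.null(dim(mat))) mat <- matrix(mat, ncol = 1, dimnames = list(names(mat)))
  if (nrow(mat) == 0) abort("empty matrix")
  if (is.null(rownames(mat))) abort("matrix must have gene ids as rownames")
  mat <- mat[order(rownames(mat), method = "radix"), , drop = FALSE]
  if (nrow(mat) == 1) return(rownames(mat))
  hc <- hclust(dist(mat, method = "euclidean"), method = "average")
  rownames(mat)[hc$order]
}

#' Compare screens on IGTIOB scores of shared significant genes
#'
#' Builds the cross-screen comparison: the union of genes with `q < alpha` in
#' at least one screen, their IGTIOB score and q-value per screen, and a
#' deterministic hierarchical clustering of genes on their IGTIOB profiles
#' (the heat-map row order). The enrichment q-value ranks hits within a
#' screen but depends on screen-specific depth, so the orientation-bias score
#' — computed only from the sorted population — is what is compared across
#' screens. Missing IGTIOB scores (genes without intronic insertions in a
#' screen) are imputed as 0 for clustering and flagged.
#'
#' @param results_list list of tibbles from [screen_enrichment()]; screen ids
#'   are taken from their `screen_id` columns.
#' @param alpha FDR inclusion threshold (strict), default 0.01.
#' @return A `screen_comparison`: list with `screen_ids`, `genes` (leaf
#'   order), `igtiob_matrix`, `igtiob_missing` (logical matrix), `q_matrix`.
#' @export
compare_screens <- function(results_list, alpha = 0.01) {
  screen_ids <- vapply(results_list, function(r) r$screen_id[1], character(1))
  if (anyDuplicated(screen_ids)) abort("screen ids must be distinct")
  genes <- union_significant(results_list, alpha)
  if (length(genes) == 0) {
    empty <- matrix(numeric(0), nrow = 0, ncol = length(screen_ids),
                    dimnames = list(NULL, screen_ids))
    return(structure(list(screen_ids = screen_ids, genes = character(0),
                          igtiob_matrix = empty,
                          igtiob_missing = empty > 0, q_matrix = empty),
                     class = "screen_comparison"))
  }
  pull_col <- function(col) {
    vapply(results_list, function(r) {
      v <- r[[col]][match(genes, r$gene_id)]
      as.numeric(v)
    }, numeric(length(genes)))
  }
  ig <- matrix(pull_col("igtiob"), ncol = length(screen_ids),
               dimnames = list(genes, screen_ids))
  qm <- matrix(pull_col("q"), ncol = length(screen_ids),
               dimnames = list(genes, screen_ids))
  missing <- is.na(ig)
  ig_imputed <- ifelse(missing, 0, ig)
  leaf <- cluster_rows(ig_imputed)
  structure(list(screen_ids = screen_ids,
                 genes = leaf,
                 igtiob_matrix = ig_imputed[leaf, , drop = FALSE],
                 igtiob_missing = missing[leaf, , drop = FALSE],
                 q_matrix = qm[leaf, , drop = FALSE]),
            class = "screen_comparison")
}

#' @export
print.screen_comparison <- function(x, ...) {
  cat("screen_comparison:", length(x$genes), "genes x",
      length(x$screen_ids), "screens (", paste(x$screen_ids, collapse = ", "),
      ")\n")
  invisible(x)
}

#' Write a screen comparison as a heat-map TSV
#'
#' One row per gene in leaf order; one IGTIOB column and one q column per
#' screen (imputed IGTIOB values carry an `igtiob_missing_*` flag column).
#'
#' @param comparison a `screen_comparison`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_comparison_tsv <- function(comparison, path) {
  stopifnot(inherits(comparison, "screen_comparison"))
  df <- data.frame(gene_id = comparison$genes)
  for (s in comparison$screen_ids) {
    df[[paste0("igtiob_", s)]] <- comparison$igtiob_matrix[, s]
    df[[paste0("igtiob_missing_", s)]] <- comparison$igtiob_missing[, s]
    df[[paste0("q_", s)]] <- comparison$q_matrix[, s]
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
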