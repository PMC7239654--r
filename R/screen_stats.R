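#' Tabulate per-gene insertion counts for one screen
#'
#' Counts, for every annotated gene, the unique inactivating insertions in the
#' sorted population (`n_inactivating`), the unique sense and antisense
#' intronic insertions in the sorted population (`n_sense_intronic`,
#' `n_antisense_intronic`), and the unique insertions of any class in the
#' control population (`n_control`). Population totals (`total_sorted`,
#' `total_control`) count all unique insertions genome-wide, intergenic
#' included, and are repeated on every row.
#'
#' @param sorted_ds `insertion_dataset` with `population == "sorted"`.
#' @param control_ds `insertion_dataset` with `population == "control"`.
#' @param annotation a [genome_annotation].
#' @return Tibble with one row per annotated gene (zero-count genes included).
#' @export
tabulate_screen <- function(sorted_ds, control_ds, annotation) {
  stopifnot(inherits(sorted_ds, "insertion_dataset"),
            inherits(control_ds, "insertion_dataset"))
  if (sorted_ds$population != "sorted" || control_ds$population != "control") {
    abort("expected population labels 'sorted' and 'control'")
  }
  calls_s <- classify_insertions(sorted_ds, annotation)
  calls_c <- classify_insertions(control_ds, annotation)

  genic_s <- calls_s[!is.na(calls_s$gene_id), ]
  per_gene_s <- dplyr::summarise(
    dplyr::group_by(genic_s, .data$gene_id),
    n_inactivating = sum(.data$classification == "inactivating"),
    n_sense_intronic = sum(.data$feature == "intron" & .data$orientation == "sense"),
    n_antisense_intronic = sum(.data$feature == "intron" & .data$orientation == "antisense"),
    .groups = "drop")
  genic_c <- calls_c[!is.na(calls_c$gene_id), ]
  per_gene_c <- dplyr::summarise(dplyr::group_by(genic_c, .data$gene_id),
                                 n_control = dplyr::n(), .groups = "drop")

  out <- tibble(gene_id = annotation$genes$gene_id)
  out <- dplyr::left_join(out, per_gene_s, by = "gene_id")
  out <- dplyr::left_join(out, per_gene_c, by = "gene_id")
  out[is.na(out)] <- 0L
  out$total_sorted <- nrow(sorted_ds$insertions)
  out$total_control <- nrow(control_ds$insertions)
  out
}

#' One-sided exact enrichment test
#'
#' Tests whether inactivating insertions in a gene are enriched in the sorted
#' population relative to insertions of any class in that gene in the control
#' population, given the population totals. This is the one-sided (greater)
#' Fisher exact test on the 2x2 table
#' `[[a, T_s - a], [g, T_c - g]]`: the p-value is the hypergeometric
#' upper-tail probability of drawing at least `a` of the `a + g` in-gene
#' insertions into the sorted margin.
#'
#' @param a unique inactivating insertions in the gene, sorted population.
#' @param total_sorted total unique insertions, sorted population.
#' @param g unique insertions in the gene, control population.
#' @param total_control total unique insertions, control population.
#' @return p-value(s) in `[0, 1]`; vectorized over the four arguments.
#' @examples
#' enrichment_test(3, 10, 0, 10)  # choose(17, 7) / choose(20, 10)
#' @export
enrichment_test <- function(a, total_sorted, g, total_control) {
  if (any(total_sorted <= 0) || any(total_control <= 0)) {
    abort("population totals must be positive")
  }
  if (any(a > total_sorted) || any(g > total_control)) {
    abort("in-gene counts cannot exceed population totals")
  }
  if (any(a < 0) || any(g < 0)) abort("counts must be non-negative")
  # P(X >= a), X ~ Hypergeometric(white = a+g, black = N-(a+g), drawn = T_s)
  phyper(a - 1, m = a + g, n = total_sorted + total_control - a - g,
         k = total_sorted, lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted p-values: `q_(i) = min_{j >= i} p_(j) * m / j`, capped at
#' 1, returned in the input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Vector of adjusted values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0) || any(p > 1)) abort("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Intronic gene-trap insertion orientation bias (IGTIOB) score
#'
#' Signed bias of intronic insertion orientation in the sorted population:
#' `(S - A) / (S + A)` where `S` and `A` are the unique sense and antisense
#' intronic insertion counts in the gene. Ranges over `[-1, 1]`; positive
#' values indicate selection for gene inactivation (sense-orientation
#' splice-acceptor capture). Undefined (`NA`) when the gene has no intronic
#' insertions.
#'
#' @param sense,antisense non-negative counts; vectorized.
#' @return Score(s) in `[-1, 1]`, `NA` where `sense + antisense == 0`.
#' @export
igtiob <- function(sense, antisense) {
  if (any(sense < 0) || any(antisense < 0)) abort("counts must be non-negative")
  total <- sense + antisense
  ifelse(total > 0, (sense - antisense) / total, NA_real_)
}

#' Per-gene enrichment analysis of one screen
#'
#' Runs the full single-screen analysis: per-gene tabulation, one-sided exact
#' enrichment test of inactivating insertions (sorted vs control), BH-FDR
#' correction across the whole gene universe, IGTIOB scoring, and hit calling
#' at the two strict significance thresholds (q < 0.01 for the comparative
#' analysis, q < 1e-4 for top hits).
#'
#' @inheritParams tabulate_screen
#' @return Tibble, one row per gene, ordered by `q` then `gene_id`: counts plus
#'   `p`, `q`, `igtiob`, `hit_q01`, `hit_q1e4`, and `screen_id`.
#' @export
screen_enrichment <- function(sorted_ds, control_ds, annotation) {
  counts <- tabulate_screen(sorted_ds, control_ds, annotation)
  if (counts$total_sorted[1] > 0 && counts$total_control[1] > 0) {
    counts$p <- enrichment_test(counts$n_inactivating, counts$total_sorted,
                                counts$n_control, counts$total_control)
  } else {
    counts$p <- rep(1, nrow(counts))
  }
  counts$q <- bh_fdr(counts$p)
  counts$igtiob <- igtiob(counts$n_sense_intronic, counts$n_antisense_intronic)
  counts$hit_q01 <- counts$q < 0.01
  counts$hit_q1e4 <- counts$q < 1e-4
  counts$screen_id <- sorted_ds$screen_id
  counts[order(counts$q, counts$gene_id, method = "radix"), ]
}

#' Circle-plot table for a screen
#'
#' Data behind the per-screen circle plot: genes in seeded random order along
#' x, significance as `-log10(q)` on y, and circle diameter proportional to
#' the number of unique inactivating insertions in the sorted population.
#'
#' @param results tibble from [screen_enrichment()].
#' @param seed integer seed for the random gene order.
#' @param diameter_scale multiplier `k` so that `diameter = k * n_inactivating`.
#' @param q_floor minimum q before taking `-log10`, guards against zero.
#' @return Tibble with `gene_id`, `x_rank`, `y`, `diameter`.
#' @export
circle_plot_table <- function(results, seed, diameter_scale = 1,
                              q_floor = 1e-300) {
  if (nrow(results) == 0) abort("empty results table")
  res <- results[order(results$gene_id, method = "radix"), ]
  perm <- withr::with_seed(seed, sample.int(nrow(res)))
  tibble(gene_id = res$gene_id,
         x_rank = perm,
         y = -log10(pmax(res$q, q_floor)),
         diameter = diameter_scale * res$n_inactivating)
}

#' Write a ranked screen result table as TSV
#'
#' @param results tibble from [screen_enrichment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_screen_results <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
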