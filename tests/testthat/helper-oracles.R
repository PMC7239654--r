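# Independent oracles and tiny fixtures shared across the suite. These stay
# deliberately naive (full enumeration, per-interval loops) so they check the
# vectorized implementations from the outside.

# Upper-tail hypergeometric probability by full enumeration over the support
# of the 2x2 table [[a, Ts - a], [g, Tc - g]] with fixed margins.
enum_enrichment_p <- function(a, Ts, g, Tc) {
  K <- a + g
  N <- Ts + Tc
  support <- max(0, K - Tc):min(K, Ts)
  probs <- choose(Ts, support) * choose(Tc, K - support) / choose(N, K)
  sum(probs[support >= a])
}

# Benjamini-Hochberg step-up by the textbook formula:
# q_(i) = min_{j >= i} p_(j) * m / j, returned in input order.
stepup_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(ranked)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Brute-force insertion classification: loop every gene and every exon.
brute_classify <- function(chrom, pos, strand, annotation) {
  out <- list()
  for (i in seq_len(nrow(annotation$genes))) {
    g <- annotation$genes[i, ]
    if (g$chrom != chrom || pos < g$start || pos >= g$end) next
    ex <- annotation$exons[annotation$exons$gene_id == g$gene_id, ]
    in_exon <- any(pos >= ex$start & pos < ex$end)
    orientation <- if (strand == g$strand) "sense" else "antisense"
    feature <- if (in_exon) "exon" else "intron"
    classification <- if (in_exon || orientation == "sense") "inactivating"
                      else "non_inactivating"
    out[[length(out) + 1]] <- data.frame(
      gene_id = g$gene_id, feature = feature, orientation = orientation,
      classification = classification, stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(gene_id = NA_character_, feature = "intergenic",
                      orientation = "not_applicable",
                      classification = "intergenic", stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Two genes on chr1: geneA (+, exons [100,200), [300,400)) and
# geneB (-, single exon [600,700)).
toy_annotation <- function(chrom_length = 1000) {
  genome_annotation(
    genes = data.frame(gene_id = c("geneA", "geneB"),
                       gene_name = c("geneA", "geneB"),
                       chrom = "chr1", strand = c("+", "-")),
    exons = data.frame(gene_id = c("geneA", "geneA", "geneB"),
                       start = c(100, 300, 600), end = c(200, 400, 700)),
    chromosomes = c(chr1 = chrom_length))
}

# random non-overlapping toy annotation for property tests
random_annotation <- function(seed, n_genes = 20, chrom_length = 5e4) {
  cfg <- sim_config(seed = seed, n_genes = n_genes, chrom_length = chrom_length,
                    n_exons = c(1, 5), exon_length = c(50, 200),
                    intron_length = c(50, 400), intergenic_gap = c(50, 500))
  simulate_annotation(cfg)
}

make_dataset <- function(df, population, screen_id = "s1") {
  insertion_dataset(df, screen_id = screen_id, population = population)
}

# Ratio of gate retention rates: P(insertion kept in sorted | hit-inactivating)
# over P(kept | background), estimated from uncapped sorted/control pools.
# Expectation under the gate model is (phi + (1-phi)*eps)/phi.
gate_retention_ratio <- function(scr, ann) {
  calls_c <- classify_insertions(scr$control, ann)
  hit_inact <- unique(calls_c[!is.na(calls_c$gene_id) &
                                calls_c$gene_id %in% scr$hit_gene_ids &
                                calls_c$classification == "inactivating",
                              c("pos", "strand")])
  in_sorted <- paste(hit_inact$pos, hit_inact$strand) %in%
    paste(scr$sorted$insertions$pos, scr$sorted$insertions$strand)
  g <- nrow(hit_inact); a <- sum(in_sorted)
  T_s <- nrow(scr$sorted$insertions); T_c <- nrow(scr$control$insertions)
  p_hit <- a / g
  p_bg <- (T_s - a) / (T_c - g)
  value <- p_hit / p_bg
  # delta-method SE on the ratio of two binomial proportions
  se <- value * sqrt((1 - p_hit) / (p_hit * g) + (1 - p_bg) / (p_bg * (T_c - g)))
  list(value = value, se = se)
}

write_bed6 <- function(df, path = tempfile(fileext = ".bed")) {
  lines <- paste(df$chrom, df$pos, df$pos + 1,
                 paste0("i", seq_len(nrow(df))), 0, df$strand, sep = "\t")
  writeLines(lines, path)
  path
}
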