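test_that("per-gene tabulation matches a by-hand tally on a toy screen", {
  ann <- toy_annotation()
  # geneA (+): exon hit (either strand), sense intron, antisense intron;
  # geneB (-): one exon hit; plus one intergenic insertion in each population.
  sorted <- make_dataset(data.frame(
    chrom = "chr1",
    pos = c(150, 250, 260, 650, 500),
    strand = c("-", "+", "-", "+", "+")), "sorted")
  control <- make_dataset(data.frame(
    chrom = "chr1",
    pos = c(120, 250, 900),
    strand = c("+", "-", "-")), "control")
  counts <- tabulate_screen(sorted, control, ann)
  a <- counts[counts$gene_id == "geneA", ]
  # hand tally: exon@150 + sense-intron@250 inactivating; antisense intron@260
  expect_equal(a$n_inactivating, 2L)
  expect_equal(a$n_sense_intronic, 1L)
  expect_equal(a$n_antisense_intronic, 1L)
  expect_equal(a$n_control, 2L)  # exon@120 and intron@250 (any class counts)
  b <- counts[counts$gene_id == "geneB", ]
  expect_equal(b$n_inactivating, 1L)  # exon@650, antisense but exonic
  expect_equal(b$n_control, 0L)
  # totals include intergenic insertions
  expect_equal(unique(counts$total_sorted), 5L)
  expect_equal(unique(counts$total_control), 3L)
})

test_that("tabulation covers zero-count genes and rejects mislabeled populations", {
  ann <- toy_annotation()
  empty <- make_dataset(data.frame(chrom = character(0), pos = numeric(0),
                                   strand = character(0)), "sorted")
  empty_c <- make_dataset(data.frame(chrom = character(0), pos = numeric(0),
                                     strand = character(0)), "control")
  counts <- tabulate_screen(empty, empty_c, ann)
  expect_equal(nrow(counts), 2)
  expect_true(all(counts$n_inactivating == 0))
  expect_true(all(counts$total_sorted == 0))
  expect_error(tabulate_screen(empty_c, empty, ann), "population")
})

test_that("enrichment test equals hand-derived hypergeometric tails", {
  expect_equal(enrichment_test(0, 5, 3, 7), 1)
  expect_equal(enrichment_test(1, 1, 0, 1), 0.5)
  expect_equal(enrichment_test(3, 10, 0, 10), choose(17, 7) / choose(20, 10))
  expect_error(enrichment_test(5, 3, 0, 10), "exceed")
  expect_error(enrichment_test(1, 0, 0, 10), "positive")
})

test_that("enrichment test matches full enumeration for all small tables", {
  worst <- 0
  for (Ts in 1:12) for (Tc in 1:12) {
    a <- rep(0:Ts, each = Tc + 1)
    g <- rep(0:Tc, times = Ts + 1)
    p <- enrichment_test(a, Ts, g, Tc)
    p_oracle <- mapply(enum_enrichment_p, a, Ts, g, Tc)
    worst <- max(worst, max(abs(p - p_oracle)))
  }
  expect_lt(worst, 1e-12)
})

test_that("enrichment test agrees with the one-sided Fisher exact test", {
  set.seed(3)
  for (i in 1:25) {
    Ts <- sample(5:200, 1); Tc <- sample(5:200, 1)
    a <- sample(0:min(Ts, 20), 1); g <- sample(0:min(Tc, 20), 1)
    ft <- fisher.test(matrix(c(a, Ts - a, g, Tc - g), 2, byrow = TRUE),
                      alternative = "greater")
    expect_equal(enrichment_test(a, Ts, g, Tc), ft$p.value, tolerance = 1e-12)
  }
})

test_that("BH correction follows the step-up formula and is monotone", {
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 10)), rep(1, 10))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(9)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    q <- bh_fdr(p)
    expect_equal(q, stepup_bh(p))
    expect_true(all(q >= p - 1e-15))
    # decreasing any one p never increases any q
    j <- sample(length(p), 1)
    p2 <- p; p2[j] <- p[j] / 2
    expect_true(all(bh_fdr(p2) <= q + 1e-15))
  }
})

test_that("IGTIOB is the signed intronic orientation bias", {
  expect_equal(igtiob(5, 5), 0)
  expect_equal(igtiob(3, 0), 1)
  expect_equal(igtiob(7, 3), 0.4)
  expect_true(is.na(igtiob(0, 0)))
  expect_error(igtiob(-1, 2), "non-negative")
  # antisymmetry and boundedness over a grid of counts
  s <- rep(0:8, each = 9); a <- rep(0:8, times = 9)
  sc <- igtiob(s, a)
  expect_equal(sc, -igtiob(a, s))
  expect_true(all(abs(sc) <= 1, na.rm = TRUE))
})

test_that("screen_enrichment ties counts, p, q and hit flags together", {
  ann <- toy_annotation()
  sorted <- make_dataset(data.frame(
    chrom = "chr1", pos = c(150, 110, 320, 250), strand = c("+", "-", "+", "+")),
    "sorted")
  control <- make_dataset(data.frame(
    chrom = "chr1", pos = c(650, 800), strand = c("+", "-")), "control")
  res <- screen_enrichment(sorted, control, ann)
  expect_equal(nrow(res), 2)
  a <- res[res$gene_id == "geneA", ]
  expect_equal(a$p, enrichment_test(4, 4, 0, 2))
  expect_equal(res$q, bh_fdr(res$p))
  expect_equal(res$hit_q01, res$q < 0.01)
  expect_equal(res$hit_q1e4, res$q < 1e-4)
  expect_equal(a$igtiob, 1)  # single sense intronic insertion at 250
})

test_that("circle-plot table is a seeded permutation with -log10 q heights", {
  res <- tibble::tibble(gene_id = sprintf("g%02d", 1:6),
                        q = c(0.01, 1, 1e-4, 0.5, 1, 0.2),
                        n_inactivating = c(10, 1, 25, 2, 0, 3))
  tab <- circle_plot_table(res, seed = 99, diameter_scale = 2)
  expect_equal(tab$y[tab$gene_id == "g01"], 2)
  expect_equal(tab$y[tab$gene_id == "g02"], 0)
  expect_equal(tab$diameter, 2 * res$n_inactivating[match(tab$gene_id, res$gene_id)])
  expect_setequal(tab$x_rank, 1:6)
  tab2 <- circle_plot_table(res, seed = 99, diameter_scale = 2)
  expect_identical(tab, tab2)
  tab3 <- circle_plot_table(res[sample(6), ], seed = 99)
  expect_equal(tab3$x_rank, tab$x_rank)  # order independent of input order
  # q of 0 is floored, not infinite
  res$q[1] <- 0
  expect_true(is.finite(max(circle_plot_table(res, seed = 1)$y)))
})
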