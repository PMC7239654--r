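test_that("BED6 reading uses start as the 0-based site and deduplicates", {
  path <- write_bed6(data.frame(chrom = "chr1", pos = 149, strand = "-"))
  ds <- read_insertions(path, "s1", "sorted")
  expect_equal(as.data.frame(ds$insertions),
               data.frame(chrom = "chr1", pos = 149, strand = "-"))
  expect_equal(ds$n_duplicates_dropped, 0L)

  dup <- write_bed6(data.frame(chrom = c("chr1", "chr1"), pos = c(149, 149),
                               strand = c("-", "-")))
  ds2 <- read_insertions(dup, "s1", "sorted")
  expect_equal(nrow(ds2$insertions), 1)
  expect_equal(ds2$n_duplicates_dropped, 1L)
})

test_that("empty files, missing strand, and wide intervals are handled", {
  empty <- tempfile(fileext = ".bed")
  file.create(empty)
  ds <- read_insertions(empty, "s1", "control")
  expect_equal(nrow(ds$insertions), 0)
  expect_equal(ds$n_duplicates_dropped, 0L)

  no_strand <- tempfile(fileext = ".bed")
  writeLines("chr1\t10\t11\ti1\t0", no_strand)
  expect_error(read_insertions(no_strand, "s1", "sorted"), "strand")

  wide <- tempfile(fileext = ".bed")
  writeLines("chr1\t10\t20\ti1\t0\t+", wide)
  expect_warning(ds3 <- read_insertions(wide, "s1", "sorted"), "start")
  expect_equal(ds3$insertions$pos, 10)
})

test_that("classification follows the exon/intron/orientation rules", {
  ann <- toy_annotation()
  call_one <- function(pos, strand) {
    classify_insertions(data.frame(chrom = "chr1", pos = pos, strand = strand), ann)
  }
  # exonic: inactivating in either orientation
  c1 <- call_one(150, "-")
  expect_equal(c1$feature, "exon")
  expect_equal(c1$orientation, "antisense")
  expect_equal(c1$classification, "inactivating")
  # intronic sense: inactivating
  c2 <- call_one(250, "+")
  expect_equal(c2$feature, "intron")
  expect_equal(c2$classification, "inactivating")
  # intronic antisense: non-inactivating
  c3 <- call_one(250, "-")
  expect_equal(c3$classification, "non_inactivating")
  # half-open membership: end of exon is outside the exon
  c4 <- call_one(200, "+")
  expect_equal(c4$feature, "intron")
  # outside any gene span
  c5 <- call_one(500, "+")
  expect_equal(c5$feature, "intergenic")
  expect_true(is.na(c5$gene_id))
  expect_equal(c5$orientation, "not_applicable")
  # geneB is on the minus strand: a minus-strand insertion is sense
  c6 <- call_one(650, "-")
  expect_equal(c6$orientation, "sense")
})

test_that("unknown chromosomes and out-of-bounds positions are errors", {
  ann <- toy_annotation()
  expect_error(
    classify_insertions(data.frame(chrom = "chrX", pos = 1, strand = "+"), ann),
    "chrX")
  expect_error(
    classify_insertions(data.frame(chrom = "chr1", pos = 5000, strand = "+"), ann),
    "bounds")
})

test_that("classification agrees with a brute-force oracle on random inputs", {
  ann <- random_annotation(11, n_genes = 25)
  n <- 10000
  set.seed(42)
  ins <- data.frame(chrom = "chrS",
                    pos = sample.int(unname(ann$chromosomes["chrS"]), n,
                                     replace = TRUE) - 1,
                    strand = sample(c("+", "-"), n, replace = TRUE))
  ins <- unique(ins)
  calls <- classify_insertions(ins, ann)
  oracle <- do.call(rbind, lapply(seq_len(nrow(ins)), function(i) {
    cbind(ins[i, , drop = FALSE],
          brute_classify(ins$chrom[i], ins$pos[i], ins$strand[i], ann),
          row.names = NULL)
  }))
  cols <- c("chrom", "pos", "strand", "gene_id", "feature", "orientation",
            "classification")
  sort_tab <- function(d) {
    d <- as.data.frame(d)[cols]
    d[order(d$pos, d$strand, d$gene_id, na.last = TRUE), ]
  }
  expect_equal(sort_tab(calls), sort_tab(oracle), ignore_attr = TRUE)
})

test_that("row order never changes calls and strand flips swap intron orientation", {
  ann <- random_annotation(12)
  set.seed(5)
  ins <- unique(data.frame(
    chrom = "chrS",
    pos = sample.int(unname(ann$chromosomes["chrS"]), 500, replace = TRUE) - 1,
    strand = sample(c("+", "-"), 500, replace = TRUE)))
  calls <- classify_insertions(ins, ann)
  shuffled <- classify_insertions(ins[sample(nrow(ins)), ], ann)
  expect_equal(calls, shuffled)

  flipped <- ann
  flipped$genes$strand <- ifelse(ann$genes$strand == "+", "-", "+")
  calls_f <- classify_insertions(ins, flipped)
  expect_equal(calls_f$feature, calls$feature)
  intron <- calls$feature == "intron"
  expect_equal(calls_f$orientation[intron],
               ifelse(calls$orientation[intron] == "sense", "antisense", "sense"))
  exonic <- calls$feature == "exon"
  expect_equal(calls_f$classification[exonic], calls$classification[exonic])
})

test_that("an insertion overlapping two genes yields one call per gene", {
  ann <- genome_annotation(
    genes = data.frame(gene_id = c("gA", "gB"), gene_name = c("gA", "gB"),
                       chrom = "c", strand = c("+", "-")),
    exons = data.frame(gene_id = c("gA", "gA", "gB"),
                       start = c(0, 200, 150), end = c(100, 300, 250)),
    chromosomes = c(c = 1000))
  calls <- classify_insertions(data.frame(chrom = "c", pos = 180, strand = "+"), ann)
  expect_equal(sort(calls$gene_id), c("gA", "gB"))
  expect_equal(calls$feature[calls$gene_id == "gA"], "intron")
  expect_equal(calls$feature[calls$gene_id == "gB"], "exon")
})
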