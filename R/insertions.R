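#' Read a gene-trap insertion table (BED6)
#'
#' Each row is one mapped gene-trap integration site: the BED start is the
#' 0-based insertion coordinate and the strand gives the orientation of the
#' integrated cassette. Exact duplicates on (chrom, pos, strand) are collapsed
#' and counted, since only unique insertion sites are evidence of independent
#' mutagenesis events.
#'
#' @param path tab-delimited BED6 file (chrom, start, end, name, score,
#'   strand); no header.
#' @param screen_id screen identifier carried through to results.
#' @param population `"sorted"` or `"control"`.
#' @return An `insertion_dataset`: list with `screen_id`, `population`,
#'   `insertions` (tibble chrom/pos/strand, unique rows) and
#'   `n_duplicates_dropped`.
#' @export
read_insertions <- function(path, screen_id, population = c("sorted", "control")) {
  population <- match.arg(population)
  if (!file.exists(path)) abort(paste0("insertion file not found: ", path))
  raw <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, comment.char = "#",
               colClasses = "character", quote = ""),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) NULL
      else abort(paste0("parse error in ", path, ": ", conditionMessage(e)))
    })
  if (is.null(raw) || nrow(raw) == 0) {
    return(insertion_dataset(tibble(chrom = character(0), pos = numeric(0),
                                    strand = character(0)),
                             screen_id, population, n_duplicates_dropped = 0L))
  }
  if (ncol(raw) < 6) abort("BED6 required: strand column (field 6) is missing")
  ins <- tibble(chrom = raw[[1]],
                pos = as.numeric(raw[[2]]),
                end = as.numeric(raw[[3]]),
                strand = raw[[6]])
  if (anyNA(ins$pos) || anyNA(ins$end)) abort("non-numeric start/end in BED6")
  if (!all(ins$strand %in% c("+", "-"))) {
    abort("strand column must be '+' or '-'")
  }
  if (any(ins$end != ins$pos + 1)) {
    warn("BED6 rows with end != start+1; using start as the insertion site")
  }
  ins$end <- NULL
  n_before <- nrow(ins)
  ins <- dplyr::distinct(ins)
  insertion_dataset(ins, screen_id, population,
                    n_duplicates_dropped = n_before - nrow(ins))
}

#' Construct an insertion dataset
#'
#' @param insertions tibble with columns `chrom`, `pos` (0-based), `strand`.
#' @param screen_id,population dataset labels.
#' @param n_duplicates_dropped count of collapsed duplicate rows.
#' @return An `insertion_dataset` object.
#' @export
insertion_dataset <- function(insertions, screen_id,
                              population = c("sorted", "control"),
                              n_duplicates_dropped = 0L) {
  population <- match.arg(population)
  insertions <- as_tibble(insertions)[c("chrom", "pos", "strand")]
  if (!all(insertions$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  if (anyDuplicated(insertions)) abort("insertions must be unique on (chrom, pos, strand)")
  structure(list(screen_id = screen_id, population = population,
                 insertions = insertions,
                 n_duplicates_dropped = as.integer(n_duplicates_dropped)),
            class = "insertion_dataset")
}

#' @export
print.insertion_dataset <- function(x, ...) {
  cat("insertion_dataset:", x$screen_id, "/", x$population, "-",
      nrow(x$insertions), "unique insertions (",
      x$n_duplicates_dropped, "duplicates dropped)\n")
  invisible(x)
}

#' Write an insertion dataset as BED6
#'
#' @param dataset an `insertion_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_insertions_bed <- function(dataset, path) {
  stopifnot(inherits(dataset, "insertion_dataset"))
  ins <- dataset$insertions
  lines <- paste(ins$chrom, format_coord(ins$pos), format_coord(ins$pos + 1),
                 paste0("ins", seq_len(nrow(ins))), 0, ins$strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Classify gene-trap insertions against gene models
#'
#' Determines, for every insertion, the gene(s) it falls in, the feature
#' (exon/intron/intergenic), the orientation relative to the gene's strand
#' (sense = same strand), and whether the insertion is gene-inactivating.
#' Exonic insertions are inactivating regardless of orientation; intronic
#' insertions are inactivating only in the sense orientation (splice-acceptor
#' capture); intergenic insertions are neither. An insertion overlapping
#' several genes yields one call per gene; "within a gene" means within the
#' union-exon extent, so flanking/promoter regions are not counted.
#'
#' @param insertions an `insertion_dataset` or a tibble with `chrom`, `pos`,
#'   `strand`.
#' @param annotation a [genome_annotation].
#' @return A tibble with columns `chrom`, `pos`, `strand`, `gene_id` (NA when
#'   intergenic), `feature` (`exon`/`intron`/`intergenic`), `orientation`
#'   (`sense`/`antisense`/`not_applicable`), `classification`
#'   (`inactivating`/`non_inactivating`/`intergenic`), one row per
#'   insertion-gene pair plus one row per intergenic insertion.
#' @export
classify_insertions <- function(insertions, annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  if (inherits(insertions, "insertion_dataset")) insertions <- insertions$insertions
  insertions <- as_tibble(insertions)
  empty <- tibble(chrom = character(0), pos = numeric(0), strand = character(0),
                  gene_id = character(0), feature = character(0),
                  orientation = character(0), classification = character(0))
  if (nrow(insertions) == 0) return(empty)
  unknown <- setdiff(unique(insertions$chrom), names(annotation$chromosomes))
  if (length(unknown) > 0) {
    abort(paste0("chromosome(s) absent from annotation: ",
                 paste(unknown, collapse = ", ")))
  }
  # chromosome lengths inferred from gene extents are lower bounds only, so
  # the upper-bound check applies just when true lengths were declared
  beyond <- if (isTRUE(annotation$lengths_inferred)) FALSE else
    any(insertions$pos >= annotation$chromosomes[insertions$chrom])
  if (any(insertions$pos < 0) || beyond) {
    abort("insertion position outside chromosome bounds")
  }

  ins_gr <- GenomicRanges::GRanges(
    seqnames = insertions$chrom,
    ranges = IRanges::IRanges(start = insertions$pos + 1, width = 1))
  g <- annotation$genes
  gene_gr <- GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(start = g$start + 1, end = g$end))
  e <- annotation$exons
  exon_chrom <- g$chrom[match(e$gene_id, g$gene_id)]
  exon_gr <- GenomicRanges::GRanges(
    seqnames = exon_chrom,
    ranges = IRanges::IRanges(start = e$start + 1, end = e$end))

  span_hits <- GenomicRanges::findOverlaps(ins_gr, gene_gr, ignore.strand = TRUE)
  exon_hits <- GenomicRanges::findOverlaps(ins_gr, exon_gr, ignore.strand = TRUE)
  exon_pairs <- paste(S4Vectors::queryHits(exon_hits),
                      e$gene_id[S4Vectors::subjectHits(exon_hits)])

  qi <- S4Vectors::queryHits(span_hits)
  gi <- S4Vectors::subjectHits(span_hits)
  genic <- tibble(
    chrom = insertions$chrom[qi],
    pos = insertions$pos[qi],
    strand = insertions$strand[qi],
    gene_id = g$gene_id[gi],
    feature = as.character(
      ifelse(paste(qi, g$gene_id[gi]) %in% exon_pairs, "exon", "intron")),
    orientation = as.character(
      ifelse(insertions$strand[qi] == g$strand[gi], "sense", "antisense")))
  genic$classification <- as.character(ifelse(
    genic$feature == "exon" | genic$orientation == "sense",
    "inactivating", "non_inactivating"))

  inter_idx <- setdiff(seq_len(nrow(insertions)), unique(qi))
  intergenic <- tibble(
    chrom = insertions$chrom[inter_idx],
    pos = insertions$pos[inter_idx],
    strand = insertions$strand[inter_idx],
    gene_id = NA_character_,
    feature = "intergenic",
    orientation = "not_applicable",
    classification = "intergenic")

  calls <- dplyr::bind_rows(genic, intergenic)
  calls[order(calls$chrom, calls$pos, calls$strand, calls$gene_id,
              method = "radix", na.last = TRUE), ]
}

#' Write classification calls as TSV
#'
#' @param calls tibble from [classify_insertions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}
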