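#' Strand-aware genome annotation
#'
#' Container for gene models used throughout the screen analysis. All
#' coordinates are 0-based half-open (`[start, end)`), matching BED. Exons of
#' all transcripts of a gene are unioned on construction, and the gene span is
#' clipped to the exon extent (first exon start to last exon end), so that
#' exons and introns tile the span exactly.
#'
#' @param genes tibble/data.frame with columns `gene_id`, `gene_name`, `chrom`,
#'   `strand` (`"+"` or `"-"`).
#' @param exons tibble/data.frame with columns `gene_id`, `start`, `end`
#'   (0-based half-open); possibly-overlapping exon records are merged per gene.
#' @param chromosomes named numeric vector of chromosome lengths (bp). If
#'   `NULL`, each length is inferred as the maximum annotated end on that
#'   chromosome.
#' @return An object of class `genome_annotation`: a list with elements
#'   `chromosomes` (named numeric), `genes` (tibble with `gene_id`,
#'   `gene_name`, `chrom`, `strand`, `start`, `end`), `exons` (tibble with
#'   `gene_id`, `start`, `end`, sorted, disjoint within gene), and
#'   `lengths_inferred` (`TRUE` when chromosome lengths were inferred from
#'   gene extents and are therefore lower bounds only).
#' @export
genome_annotation <- function(genes, exons, chromosomes = NULL) {
  genes <- as_tibble(genes)
  exons <- as_tibble(exons)
  required <- c("gene_id", "gene_name", "chrom", "strand")
  if (!all(required %in% names(genes))) {
    abort(paste0("`genes` must have columns: ", paste(required, collapse = ", ")))
  }
  if (!all(c("gene_id", "start", "end") %in% names(exons))) {
    abort("`exons` must have columns gene_id, start, end")
  }
  if (anyDuplicated(genes$gene_id)) {
    abort(paste0("duplicated gene_id: ",
                 paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", ")))
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    abort("gene strand must be '+' or '-'")
  }
  missing_exons <- setdiff(genes$gene_id, exons$gene_id)
  if (length(missing_exons) > 0) {
    abort(paste0("gene(s) with no exons: ", paste(missing_exons, collapse = ", ")))
  }
  if (any(exons$end <= exons$start)) {
    abort("exon intervals must satisfy start < end")
  }
  exons <- merge_exon_union(exons)
  span <- dplyr::summarise(dplyr::group_by(exons, .data$gene_id),
                           start = min(.data$start), end = max(.data$end),
                           .groups = "drop")
  genes <- dplyr::left_join(genes[required], span, by = "gene_id")
  genes <- dplyr::arrange(genes, .data$chrom, .data$start, .data$gene_id)
  exons <- exons[order(match(exons$gene_id, genes$gene_id), exons$start), ]

  inferred <- is.null(chromosomes)
  if (inferred) {
    chromosomes <- tapply(genes$end, genes$chrom, max)
    chromosomes <- setNames(as.numeric(chromosomes), names(chromosomes))
  }
  bad <- genes$chrom %in% names(chromosomes) &
    genes$end > chromosomes[genes$chrom]
  if (any(bad) || !all(genes$chrom %in% names(chromosomes))) {
    abort("gene span outside its chromosome's [0, length)")
  }
  if (any(genes$start < 0)) abort("negative coordinates not allowed")

  structure(list(chromosomes = chromosomes, genes = genes, exons = exons,
                 lengths_inferred = inferred),
            class = "genome_annotation")
}

# Merge overlapping/duplicated exon records into a union-exon set per gene
# (sweep over sorted endpoints via IRanges::reduce).
merge_exon_union <- function(exons) {
  if (nrow(exons) == 0) {
    return(tibble(gene_id = character(0), start = numeric(0), end = numeric(0)))
  }
  by_gene <- split(exons, exons$gene_id)
  merged <- lapply(names(by_gene), function(g) {
    e <- by_gene[[g]]
    ir <- IRanges::reduce(IRanges::IRanges(start = e$start + 1, end = e$end))
    tibble(gene_id = g,
           start = BiocGenerics::start(ir) - 1,
           end = BiocGenerics::end(ir))
  })
  dplyr::bind_rows(merged)
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$genes), "genes on",
      length(x$chromosomes), "chromosome(s),",
      nrow(x$exons), "union exons\n")
  invisible(x)
}

#' Validate a genome annotation
#'
#' Checks all structural invariants: positive-width sorted disjoint exons
#' contained in the gene span, span within chromosome bounds, unique gene ids,
#' strands restricted to `+`/`-`.
#'
#' @param annotation a [genome_annotation] object.
#' @return `TRUE` invisibly; aborts with a message on the first violation.
#' @export
validate_annotation <- function(annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  g <- annotation$genes
  e <- annotation$exons
  if (anyDuplicated(g$gene_id)) abort("duplicate gene_id")
  if (!all(g$strand %in% c("+", "-"))) abort("invalid strand")
  if (any(g$start >= g$end)) abort("gene span must have start < end")
  if (any(e$start >= e$end)) abort("exon must have start < end")
  if (!all(g$chrom %in% names(annotation$chromosomes))) {
    abort("gene on unknown chromosome")
  }
  if (any(g$start < 0) || any(g$end > annotation$chromosomes[g$chrom])) {
    abort("gene span outside chromosome bounds")
  }
  for (gid in g$gene_id) {
    ge <- e[e$gene_id == gid, ]
    if (nrow(ge) == 0) abort(paste0("gene with no exons: ", gid))
    if (is.unsorted(ge$start, strictly = TRUE) && nrow(ge) > 1) {
      abort(paste0("exons not sorted for gene ", gid))
    }
    if (nrow(ge) > 1 && any(ge$start[-1] < ge$end[-nrow(ge)])) {
      abort(paste0("overlapping exons for gene ", gid))
    }
    row <- g[g$gene_id == gid, ]
    if (min(ge$start) != row$start || max(ge$end) != row$end) {
      abort(paste0("span not clipped to exon extent for gene ", gid))
    }
  }
  invisible(TRUE)
}

#' Read a gene annotation
#'
#' Reads GTF, GFF3 or the package's BED12 dialect and normalizes everything to
#' a single convention: 0-based half-open intervals, one gene model per
#' `gene_id` with a union-exon set merged across transcripts. GTF/GFF3
#' coordinates (1-based inclusive) are converted on read; for GFF3, exons are
#' assigned to genes by resolving `Parent` chains through transcript records.
#'
#' @param path annotation file path.
#' @param format `"auto"` (by extension), `"gtf"`, `"gff3"` or `"bed12"`.
#' @param chrom_lengths optional named vector of chromosome lengths; inferred
#'   from the annotation when absent.
#' @return A [genome_annotation].
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t400\tgeneA\t0\t+\t100\t400\t0\t2\t100,100\t0,200", bed)
#' ann <- read_annotation(bed)
#' ann$exons
#' @export
read_annotation <- function(path, format = c("auto", "gtf", "gff3", "bed12"),
                            chrom_lengths = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("annotation file not found: ", path))
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     gtf = "gtf", gff = "gff3", gff3 = "gff3", bed = "bed12",
                     abort("cannot infer annotation format from extension; pass `format`"))
  }
  if (format == "bed12") {
    return(read_bed12_annotation(path, chrom_lengths))
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = if (format == "gtf") "gtf" else "gff3"),
    error = function(e) abort(paste0("parse error in ", path, ": ", conditionMessage(e)))
  )
  mc <- S4Vectors::mcols(gr)
  is_exon <- !is.na(mc$type) & tolower(as.character(mc$type)) == "exon"
  if (!any(is_exon)) abort("no exon features found in annotation")

  if (format == "gtf") {
    exon_gene <- as.character(mc$gene_id[is_exon])
  } else {
    exon_gene <- gff3_exon_gene_ids(gr, is_exon)
  }
  exon_gr <- gr[is_exon]
  exons <- tibble(gene_id = exon_gene,
                  start = BiocGenerics::start(exon_gr) - 1,
                  end = BiocGenerics::end(exon_gr))

  # gene-level metadata: prefer explicit gene records, fall back to exon rows
  is_gene <- !is.na(mc$type) & tolower(as.character(mc$type)) == "gene"
  if (any(is_gene)) {
    gmc <- S4Vectors::mcols(gr[is_gene])
    gid <- if (format == "gtf") as.character(gmc$gene_id) else as.character(gmc$ID)
    gname <- gene_name_or_id(gmc, gid)
    genes <- tibble(gene_id = gid, gene_name = gname,
                    chrom = as.character(GenomicRanges::seqnames(gr[is_gene])),
                    strand = as.character(BiocGenerics::strand(gr[is_gene])))
    orphan <- setdiff(genes$gene_id, exons$gene_id)
    if (length(orphan) > 0) {
      abort(paste0("gene(s) with no exons: ", paste(orphan, collapse = ", ")))
    }
    genes <- genes[genes$gene_id %in% exons$gene_id, ]
  } else {
    emc <- S4Vectors::mcols(exon_gr)
    genes <- dplyr::distinct(tibble(
      gene_id = exon_gene,
      gene_name = gene_name_or_id(emc, exon_gene),
      chrom = as.character(GenomicRanges::seqnames(exon_gr)),
      strand = as.character(BiocGenerics::strand(exon_gr))))
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    abort("unstranded gene records are not supported")
  }
  genome_annotation(genes, exons, chromosomes = chrom_lengths)
}

gene_name_or_id <- function(mc, gid) {
  nm <- if ("gene_name" %in% names(mc)) as.character(mc$gene_name)
        else if ("Name" %in% names(mc)) as.character(mc$Name)
        else NA_character_
  ifelse(is.na(nm) | !nzchar(nm), gid, nm)
}

# Resolve each GFF3 exon's gene by walking Parent pointers (exon -> mRNA ->
# gene). Exons parented directly on genes are accepted too.
gff3_exon_gene_ids <- function(gr, is_exon) {
  mc <- S4Vectors::mcols(gr)
  ids <- as.character(mc$ID)
  parent_of <- vapply(seq_along(gr), function(i) {
    p <- mc$Parent[[i]]
    if (length(p) == 0) NA_character_ else as.character(p)[1]
  }, character(1))
  types <- tolower(as.character(mc$type))
  id_type <- setNames(types, ids)
  id_parent <- setNames(parent_of, ids)
  resolve <- function(node) {
    for (step in 1:10) {
      if (is.na(node)) return(NA_character_)
      if (!is.na(id_type[node]) && id_type[node] == "gene") return(node)
      nxt <- id_parent[node]
      if (is.na(nxt)) return(node)  # topmost ancestor stands in for the gene
      node <- unname(nxt)
    }
    NA_character_
  }
  out <- vapply(parent_of[is_exon], resolve, character(1))
  if (anyNA(out)) abort("GFF3 exon with unresolvable Parent chain")
  unname(out)
}

read_bed12_annotation <- function(path, chrom_lengths = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")]
  if (length(lines) == 0) abort("empty BED12 file")
  genes <- vector("list", length(lines))
  exons <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12) {
      abort(paste0("parse error at line ", i, ": expected 12 tab-separated fields, got ",
                   length(f)))
    }
    start <- suppressWarnings(as.numeric(f[2]))
    n_blocks <- suppressWarnings(as.integer(f[10]))
    sizes <- suppressWarnings(as.numeric(strsplit(f[11], ",")[[1]]))
    offsets <- suppressWarnings(as.numeric(strsplit(f[12], ",")[[1]]))
    if (anyNA(c(start, n_blocks, sizes, offsets)) ||
        length(sizes) != n_blocks || length(offsets) != n_blocks) {
      abort(paste0("parse error at line ", i, ": malformed block fields"))
    }
    if (n_blocks == 0) abort(paste0("gene with no exons: ", f[4]))
    genes[[i]] <- tibble(gene_id = f[4], gene_name = f[4],
                         chrom = f[1], strand = f[6])
    block_starts <- start + offsets
    exons[[i]] <- tibble(gene_id = f[4],
                         start = block_starts, end = block_starts + sizes)
  }
  genome_annotation(dplyr::bind_rows(genes), dplyr::bind_rows(exons),
                    chromosomes = chrom_lengths)
}

#' Write an annotation as BED12
#'
#' One record per gene; blocks are the union exons. Re-reading the file with
#' [read_annotation()] reproduces identical intervals.
#'
#' @param annotation a [genome_annotation].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(annotation, path) {
  stopifnot(inherits(annotation, "genome_annotation"))
  g <- annotation$genes
  lines <- vapply(seq_len(nrow(g)), function(i) {
    e <- annotation$exons[annotation$exons$gene_id == g$gene_id[i], ]
    paste(g$chrom[i], format_coord(g$start[i]), format_coord(g$end[i]),
          g$gene_id[i], 0, g$strand[i],
          format_coord(g$start[i]), format_coord(g$end[i]), 0, nrow(e),
          paste0(paste(format_coord(e$end - e$start), collapse = ","), ","),
          paste0(paste(format_coord(e$start - g$start[i]), collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Intron intervals of a gene
#'
#' Gaps between consecutive union exons, in 0-based half-open coordinates.
#' Exons and introns together tile the gene span exactly.
#'
#' @param annotation a [genome_annotation].
#' @param gene_id gene identifier present in the annotation.
#' @return A tibble with columns `start`, `end`; zero rows for single-exon
#'   genes or abutting exons.
#' @export
gene_introns <- function(annotation, gene_id) {
  stopifnot(inherits(annotation, "genome_annotation"))
  e <- annotation$exons[annotation$exons$gene_id == gene_id, ]
  if (nrow(e) == 0) abort(paste0("unknown gene: ", gene_id))
  introns_from_exons(e$start, e$end)
}

introns_from_exons <- function(starts, ends) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  n <- length(starts)
  if (n < 2) return(tibble(start = numeric(0), end = numeric(0)))
  gaps <- tibble(start = ends[-n], end = starts[-1])
  gaps[gaps$end > gaps$start, ]
}
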