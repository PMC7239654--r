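#' Configuration for synthetic screen simulation
#'
#' Bundles the generative parameters for [simulate_annotation()] and
#' [simulate_screen()]. The defaults emulate a scaled-down haploid gene-trap
#' reporter screen: each mutagenized cell carries one gene-trap insertion at a
#' uniform genomic position with random orientation; a cell falls into the
#' FACS gate (lowest ~10% reporter fluorescence) with probability
#' `gate_fraction`, raised by `penetrance` when its insertion inactivates a
#' planted hit gene; sequencing of the gated and unsorted pools recovers
#' unique insertion sites up to the depth caps.
#'
#' @param seed integer master seed; the annotation stream uses `seed`, the
#'   screen stream `seed + 1` so the two draws are decoupled.
#' @param n_genes number of non-overlapping genes to place.
#' @param chrom,chrom_length simulated chromosome name and length (bp).
#' @param n_exons integer range (min, max) of exons per gene.
#' @param exon_length,intron_length,intergenic_gap length ranges (bp).
#' @param n_cells number of mutagenized cells (one insertion each).
#' @param gate_fraction probability that a cell without a hit-inactivating
#'   insertion falls in the sorted gate (the gate width, default 0.1).
#' @param penetrance extra gate probability mass for cells whose insertion
#'   inactivates a planted hit gene: their gate probability is
#'   `gate_fraction + (1 - gate_fraction) * penetrance`.
#' @param orientation_bias probability that an intronic insertion in a hit
#'   gene is placed in the sense orientation in the pre-sort library (0.5 =
#'   unbiased; selection alone then produces the post-sort sense excess).
#' @param n_hits number of planted hit genes (chosen at random among the
#'   simulated genes) when `hit_gene_ids` is `NULL`.
#' @param hit_gene_ids explicit planted hit gene ids, or `NULL`.
#' @param depth_sorted,depth_control maximum number of unique insertions
#'   reported per population; when the pool yields fewer, all are reported.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_genes = 100, chrom = "chrS",
                       chrom_length = 2e6,
                       n_exons = c(2, 8), exon_length = c(100, 300),
                       intron_length = c(200, 1500),
                       intergenic_gap = c(500, 3000),
                       n_cells = 5e4, gate_fraction = 0.1, penetrance = 0.9,
                       orientation_bias = 0.5,
                       n_hits = 5, hit_gene_ids = NULL,
                       depth_sorted = 1e4, depth_control = 2e4) {
  if (gate_fraction <= 0 || gate_fraction >= 1) abort("gate_fraction must be in (0, 1)")
  if (penetrance < 0 || penetrance > 1) abort("penetrance must be in [0, 1]")
  if (orientation_bias < 0 || orientation_bias > 1) {
    abort("orientation_bias must be in [0, 1]")
  }
  if (n_genes < 0 || n_cells < 1 || chrom_length < 1) abort("invalid sizes")
  structure(list(seed = as.integer(seed), n_genes = n_genes, chrom = chrom,
                 chrom_length = chrom_length, n_exons = n_exons,
                 exon_length = exon_length, intron_length = intron_length,
                 intergenic_gap = intergenic_gap, n_cells = n_cells,
                 gate_fraction = gate_fraction, penetrance = penetrance,
                 orientation_bias = orientation_bias, n_hits = n_hits,
                 hit_gene_ids = hit_gene_ids, depth_sorted = depth_sorted,
                 depth_control = depth_control),
            class = "sim_config")
}

#' Simulate a genome annotation
#'
#' Places `n_genes` non-overlapping multi-exon genes left to right on a single
#' chromosome, with uniform exon/intron/gap lengths from the configured ranges
#' and each strand drawn at random (so roughly half the genes per strand).
#' Deterministic under `config$seed`.
#'
#' @param config a [sim_config()].
#' @return A [genome_annotation].
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    genes <- vector("list", config$n_genes)
    exons <- vector("list", config$n_genes)
    cursor <- 0
    for (i in seq_len(config$n_genes)) {
      cursor <- cursor + sample(config$intergenic_gap[1]:config$intergenic_gap[2], 1)
      n_ex <- sample(config$n_exons[1]:config$n_exons[2], 1)
      ex_len <- sample(config$exon_length[1]:config$exon_length[2], n_ex, replace = TRUE)
      in_len <- if (n_ex > 1) {
        sample(config$intron_length[1]:config$intron_length[2], n_ex - 1, replace = TRUE)
      } else integer(0)
      starts <- cursor + cumsum(c(0, ex_len[-n_ex] + in_len))
      ends <- starts + ex_len
      cursor <- ends[n_ex]
      if (cursor > config$chrom_length) {
        abort(paste0(config$n_genes, " genes cannot fit in chrom_length ",
                     format_coord(config$chrom_length)))
      }
      gid <- sprintf("gene%03d", i)
      genes[[i]] <- tibble(gene_id = gid, gene_name = gid,
                           chrom = config$chrom,
                           strand = sample(c("+", "-"), 1))
      exons[[i]] <- tibble(gene_id = gid, start = starts, end = ends)
    }
    chroms <- setNames(config$chrom_length, config$chrom)
    if (config$n_genes == 0) {
      return(structure(list(
        chromosomes = chroms,
        genes = tibble(gene_id = character(0), gene_name = character(0),
                       chrom = character(0), strand = character(0),
                       start = numeric(0), end = numeric(0)),
        exons = tibble(gene_id = character(0), start = numeric(0),
                       end = numeric(0)),
        lengths_inferred = FALSE),
        class = "genome_annotation"))
    }
    genome_annotation(dplyr::bind_rows(genes), dplyr::bind_rows(exons),
                      chromosomes = chroms)
  })
}

#' Simulate a gene-trap screen with planted hits
#'
#' Generative model: every cell carries exactly one insertion (uniform
#' position, random strand). A cell enters the sorted gate with probability
#' `gate_fraction`, or `gate_fraction + (1 - gate_fraction) * penetrance` when
#' its insertion inactivates a planted hit gene (exonic in either orientation,
#' or intronic in the sense orientation). The sorted dataset holds the unique
#' insertions of gated cells, the control dataset the unique insertions of the
#' whole mutagenized pool, each subsampled to its depth cap. The expected
#' sorted/control enrichment for hit-inactivating insertions is
#' `(gate_fraction + (1 - gate_fraction) * penetrance) / gate_fraction`,
#' recorded per gene in the truth table.
#'
#' @param annotation a [genome_annotation], typically from
#'   [simulate_annotation()].
#' @param config a [sim_config()]; `hit_gene_ids` must exist in `annotation`
#'   (when `NULL`, `n_hits` genes are drawn at random).
#' @param strict_depth if `TRUE`, abort when a depth cap exceeds the unique
#'   insertions available instead of reporting them all.
#' @return List with `sorted` and `control` (`insertion_dataset`s), `truth`
#'   (tibble `gene_id`, `is_hit`, `expected_enrichment`), `hit_gene_ids`, and
#'   the echoed `config`.
#' @export
simulate_screen <- function(annotation, config, strict_depth = FALSE) {
  stopifnot(inherits(annotation, "genome_annotation"),
            inherits(config, "sim_config"))
  if (!is.null(config$hit_gene_ids)) {
    missing <- setdiff(config$hit_gene_ids, annotation$genes$gene_id)
    if (length(missing) > 0) {
      abort(paste0("hit gene(s) not in annotation: ", paste(missing, collapse = ", ")))
    }
  }
  withr::with_seed(config$seed + 1L, {
    hits <- config$hit_gene_ids
    if (is.null(hits)) {
      hits <- sort(sample(annotation$genes$gene_id, config$n_hits))
    }
    n <- config$n_cells
    pos <- sample.int(config$chrom_length, n, replace = TRUE) - 1
    strand <- sample(c("+", "-"), n, replace = TRUE)

    # pre-sort orientation bias for intronic insertions in hit genes
    if (config$orientation_bias != 0.5 && length(hits) > 0) {
      hit_introns <- dplyr::bind_rows(lapply(hits, function(g) {
        intr <- gene_introns(annotation, g)
        if (nrow(intr) > 0) {
          intr$strand <- annotation$genes$strand[annotation$genes$gene_id == g]
        }
        intr
      }))
      if (nrow(hit_introns) > 0) {
        in_intron <- interval_member(pos, hit_introns$start, hit_introns$end)
        idx <- which(in_intron > 0)
        sense_strand <- hit_introns$strand[in_intron[idx]]
        make_sense <- runif(length(idx)) < config$orientation_bias
        strand[idx] <- ifelse(make_sense, sense_strand,
                              ifelse(sense_strand == "+", "-", "+"))
      }
    }

    cells <- tibble(chrom = config$chrom, pos = pos, strand = strand)
    uniq <- dplyr::distinct(cells)
    calls <- classify_insertions(uniq, annotation)
    inactivating_hit <- unique(
      calls[!is.na(calls$gene_id) & calls$gene_id %in% hits &
              calls$classification == "inactivating", c("pos", "strand")])
    hit_flag <- paste(cells$pos, cells$strand) %in%
      paste(inactivating_hit$pos, inactivating_hit$strand)

    p_gate <- config$gate_fraction +
      (1 - config$gate_fraction) * config$penetrance * hit_flag
    gated <- runif(n) < p_gate

    take <- function(df, depth, label) {
      df <- dplyr::distinct(df)
      if (nrow(df) > depth) {
        df <- df[sort(sample.int(nrow(df), depth)), ]
      } else if (strict_depth && nrow(df) < depth) {
        abort(paste0("depth_", label, " (", format_coord(depth),
                     ") exceeds available unique insertions (", nrow(df), ")"))
      }
      df[order(df$pos, df$strand), ]
    }
    sorted_ins <- take(cells[gated, ], config$depth_sorted, "sorted")
    control_ins <- take(cells, config$depth_control, "control")

    phi <- config$gate_fraction
    expected <- (phi + (1 - phi) * config$penetrance) / phi
    truth <- tibble(gene_id = annotation$genes$gene_id,
                    is_hit = annotation$genes$gene_id %in% hits,
                    expected_enrichment = ifelse(
                      annotation$genes$gene_id %in% hits, expected, 1))

    list(sorted = insertion_dataset(sorted_ins, screen_id = "sim", "sorted"),
         control = insertion_dataset(control_ins, screen_id = "sim", "control"),
         truth = truth, hit_gene_ids = hits, config = config)
  })
}

# index of the first [start, end) interval containing each position, 0 if none
interval_member <- function(pos, starts, ends) {
  out <- integer(length(pos))
  for (j in seq_along(starts)) {
    sel <- out == 0L & pos >= starts[j] & pos < ends[j]
    out[sel] <- j
  }
  out
}

#' Write simulated screen files
#'
#' Emits the sorted and control insertion BED6 files, the ground-truth TSV and
#' a JSON echo of the configuration; byte-reproducible under the config seed.
#'
#' @param screen result of [simulate_screen()].
#' @param dir output directory (created if needed).
#' @param annotation optional [genome_annotation] to write alongside as BED12.
#' @return `dir`, invisibly.
#' @export
write_screen_files <- function(screen, dir, annotation = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_insertions_bed(screen$sorted, file.path(dir, "sorted.bed"))
  write_insertions_bed(screen$control, file.path(dir, "control.bed"))
  write.table(screen$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(screen$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(annotation)) write_bed12(annotation, file.path(dir, "annotation.bed"))
  invisible(dir)
}

#' Simulate a noisy dose-response titration
#'
#' Per-well responses on a 4PL curve with additive Gaussian noise, emulating
#' median reporter fluorescence per well.
#'
#' @param bottom,top,ec50,hill true curve parameters (`ec50` in nM > 0).
#' @param doses dose grid in nM, all positive.
#' @param noise_sd standard deviation of the additive Gaussian noise, in
#'   response units (>= 0).
#' @param n_replicates wells per dose.
#' @param seed integer seed.
#' @param sample sample id written into the table.
#' @return Tibble with columns `sample`, `dose_nM`, `replicate`, `response`.
#' @export
simulate_dose_response <- function(bottom, top, ec50, hill, doses,
                                   noise_sd = 0, n_replicates = 1, seed = 1L,
                                   sample = "sim") {
  if (ec50 <= 0) abort("ec50 must be positive")
  if (any(doses <= 0)) abort("doses must be positive")
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  grid <- expand.grid(replicate = seq_len(n_replicates), dose_nM = doses)
  mu <- fourpl(grid$dose_nM, bottom, top, log10(ec50), hill)
  noise <- withr::with_seed(seed, rnorm(nrow(grid), 0, noise_sd))
  tibble(sample = sample, dose_nM = grid$dose_nM,
         replicate = grid$replicate, response = mu + noise)
}
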