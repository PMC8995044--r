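#' Read short-read alignment intervals from BED
#'
#' One interval per aligned read (BED3/BED6); 0-based half-open.
#'
#' @param path Path to a BED file.
#' @return A tibble (read_id, chrom, start, end, strand). Strand is `*` when
#'   the file has no strand column.
#' @export
read_read_intervals <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "bed"),
    error = function(e) abort(paste("malformed BED record:", conditionMessage(e)))
  )
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm) || anyNA(nm)) nm <- paste0("read", seq_along(gr))
  tibble(
    read_id = nm,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' Count reads overlapping features
#'
#' A read counts toward a feature when it shares at least one base with it
#' (half-open intervals: an abutting read shares no base). Strandedness:
#' `"unstranded"` ignores strand, `"sense"` requires the read strand to equal
#' the feature strand, `"antisense"` requires it to differ.
#'
#' @param reads Read intervals from [read_read_intervals()].
#' @param features A data frame with `feature_id`, `chrom`, `start`, `end`,
#'   `strand` (0-based half-open).
#' @param strandedness One of "unstranded", "sense", "antisense".
#' @return `features` with an added `n_reads` column.
#' @export
count_reads_in_features <- function(reads, features,
                                    strandedness = c("unstranded", "sense", "antisense")) {
  strandedness <- match.arg(strandedness)
  features <- as_tibble(features)
  if (nrow(reads) == 0) {
    return(features |> mutate(n_reads = 0L))
  }
  r_gr <- as_granges0(reads)
  f_gr <- as_granges0(features)
  GenomicRanges::strand(r_gr) <- "*"
  GenomicRanges::strand(f_gr) <- "*"
  hits <- GenomicRanges::findOverlaps(f_gr, r_gr)
  keep <- switch(strandedness,
    unstranded = rep(TRUE, length(hits)),
    sense = features$strand[queryHits(hits)] == reads$strand[subjectHits(hits)],
    antisense = features$strand[queryHits(hits)] != reads$strand[subjectHits(hits)]
  )
  counts <- tabulate(queryHits(hits)[keep], nbins = nrow(features))
  features |> mutate(n_reads = counts)
}

#' Per-gene short-read coverage metrics: exon3/exon1 ratio and intron RPKM
#'
#' The exon3/exon1 ratio (reads overlapping exon 3 divided by reads
#' overlapping exon 1, exons in transcriptional order) is a proxy for cryptic
#' internal transcription initiation between exons 1 and 3; it is undefined
#' (`NA`) for genes with fewer than 3 exons or with fewer than
#' `min_denominator` exon-1 reads. Intron RPKM is
#' `intron_reads * 1e9 / (library_size * total_intron_length)`, where a read
#' overlapping any intron of the gene is counted once; it is undefined for
#' intronless genes. Reads spanning several features count in each
#' (the ratio is a relative proxy, not an absolute rate).
#'
#' @param reads Read intervals from [read_read_intervals()].
#' @param ann A [gene_annotation].
#' @param library_size Total mapped reads in the library; defaults to
#'   `nrow(reads)`.
#' @param strandedness Overlap policy, see [count_reads_in_features()]
#'   (default unstranded).
#' @param min_denominator Minimum exon-1 read count for the ratio (default 1).
#' @return A tibble (gene_id, exon1_reads, exon3_reads, exon3_exon1_ratio,
#'   intron_reads, total_intron_length, intron_rpkm).
#' @export
gene_coverage_metrics <- function(reads, ann, library_size = nrow(reads),
                                  strandedness = "unstranded",
                                  min_denominator = 1) {
  stopifnot(inherits(ann, "gene_annotation"))
  if (library_size <= 0) abort("library_size must be > 0")

  exon_counts <- ann$exons |>
    filter(.data$exon_rank %in% c(1L, 3L)) |>
    mutate(feature_id = paste(.data$gene_id, .data$exon_rank)) |>
    count_reads_in_features(reads = reads, strandedness = strandedness) |>
    select("gene_id", "exon_rank", "n_reads") |>
    tidyr::pivot_wider(
      names_from = "exon_rank", values_from = "n_reads",
      names_glue = "exon{exon_rank}_reads"
    )
  if (!"exon3_reads" %in% names(exon_counts)) {
    exon_counts$exon3_reads <- NA_integer_
  }

  # intron reads: each read counted once per gene even if it spans several
  # introns
  intron_counts <- if (nrow(ann$introns) > 0 && nrow(reads) > 0) {
    r_gr <- as_granges0(reads)
    i_gr <- as_granges0(ann$introns, id_col = "gene_id")
    GenomicRanges::strand(r_gr) <- "*"
    GenomicRanges::strand(i_gr) <- "*"
    hits <- GenomicRanges::findOverlaps(i_gr, r_gr)
    keep <- switch(strandedness,
      unstranded = rep(TRUE, length(hits)),
      sense = ann$introns$strand[queryHits(hits)] == reads$strand[subjectHits(hits)],
      antisense = ann$introns$strand[queryHits(hits)] != reads$strand[subjectHits(hits)]
    )
    tibble(
      gene_id = S4Vectors::mcols(i_gr)$id[queryHits(hits)][keep],
      read = subjectHits(hits)[keep]
    ) |>
      distinct() |>
      count(.data$gene_id, name = "intron_reads")
  } else {
    tibble(gene_id = character(), intron_reads = integer())
  }

  intron_len <- ann$introns |>
    group_by(.data$gene_id) |>
    summarise(total_intron_length = sum(.data$end - .data$start), .groups = "drop")

  ann$genes |>
    select("gene_id", "n_exons") |>
    left_join(exon_counts, by = "gene_id") |>
    left_join(intron_counts, by = "gene_id") |>
    left_join(intron_len, by = "gene_id") |>
    mutate(
      exon1_reads = tidyr::replace_na(.data$exon1_reads, 0L),
      exon3_reads = if_else(
        .data$n_exons >= 3L, tidyr::replace_na(.data$exon3_reads, 0L), NA_integer_
      ),
      intron_reads = if_else(
        .data$n_exons > 1L, tidyr::replace_na(.data$intron_reads, 0L), NA_integer_
      ),
      exon3_exon1_ratio = if_else(
        .data$n_exons >= 3L & .data$exon1_reads >= min_denominator &
          .data$exon1_reads > 0L,
        .data$exon3_reads / .data$exon1_reads, NA_real_
      ),
      intron_rpkm = if_else(
        .data$n_exons > 1L,
        .data$intron_reads * 1e9 / (library_size * .data$total_intron_length),
        NA_real_
      )
    ) |>
    select(
      "gene_id", "exon1_reads", "exon3_reads", "exon3_exon1_ratio",
      "intron_reads", "total_intron_length", "intron_rpkm"
    )
}
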