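#' Read spliced long-read alignments from BED12
#'
#' Each BED12 record becomes one read with its ordered aligned blocks. The
#' result is a long tibble with one row per block, carrying the read-level
#' fields on every row; `read_start_5p` is the 5'-most aligned position in
#' read orientation (leftmost block start on `+`, rightmost block end - 1
#' on `-`).
#'
#' @param path Path to a BED12 file of spliced alignments.
#' @return A tibble (read_id, chrom, strand, block_rank, start, end,
#'   read_start_5p), 0-based half-open.
#' @export
read_spliced_reads <- function(path) {
  validate_bed12_blocks(path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "bed"),
    error = function(e) abort(paste("malformed BED12 record:", conditionMessage(e)))
  )
  if (length(gr) == 0) abort("no alignments in BED file")
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm) || anyNA(nm)) nm <- paste0("read", seq_along(gr))
  blocks <- S4Vectors::mcols(gr)$blocks
  if (is.null(blocks)) {
    # plain BED: one block per read
    blocks <- IRanges::IRangesList(lapply(
      GenomicRanges::width(gr), function(w) IRanges::IRanges(1L, w)
    ))
  }
  nb <- S4Vectors::elementNROWS(blocks)
  flat <- unlist(blocks, use.names = FALSE)
  chrom_start <- rep(GenomicRanges::start(gr) - 1L, nb)
  out <- tibble(
    read_id = rep(nm, nb),
    chrom = rep(as.character(GenomicRanges::seqnames(gr)), nb),
    strand = rep(as.character(GenomicRanges::strand(gr)), nb),
    block_rank = unlist(lapply(nb, seq_len), use.names = FALSE),
    start = chrom_start + IRanges::start(flat) - 1L,
    end = chrom_start + IRanges::end(flat)
  )
  spliced_reads(out)
}

# blockCount must match the number of entries in blockSizes and blockStarts
validate_bed12_blocks <- function(path) {
  raw <- readr::read_tsv(
    path,
    col_names = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, comment = "#"
  )
  if (ncol(raw) < 12) {
    return(invisible(TRUE))
  }
  n_declared <- suppressWarnings(as.integer(raw[[10]]))
  count_fields <- function(x) lengths(strsplit(sub(",$", "", x), ","))
  bad <- which(
    is.na(n_declared) |
      count_fields(raw[[11]]) != n_declared |
      count_fields(raw[[12]]) != n_declared
  )
  if (length(bad) > 0) {
    abort(paste0(
      "BED12 blockSizes/blockStarts length mismatch for read(s): ",
      paste(head(raw[[4]][bad], 5), collapse = ", ")
    ))
  }
  invisible(TRUE)
}

#' Construct a spliced-read table from block coordinates
#'
#' Validates block ordering and computes `read_start_5p` for a long-format
#' block table. Used by [read_spliced_reads()] and the simulator.
#'
#' @param blocks A data frame with columns read_id, chrom, strand, start, end
#'   (one row per aligned block, 0-based half-open).
#' @return The validated tibble with `block_rank` and `read_start_5p` added.
#' @export
spliced_reads <- function(blocks) {
  blocks <- as_tibble(blocks)
  if (!all(blocks$strand %in% c("+", "-"))) abort("read strand must be + or -")
  if (any(blocks$start >= blocks$end)) abort("empty or inverted block")
  b <- blocks[order(blocks$read_id, blocks$start), ]
  lens <- rle(b$read_id)$lengths
  rank <- sequence(lens)
  last <- cumsum(lens)
  first_i <- last - lens + 1L
  bad <- rank > 1L & b$start < c(-1L, b$end[-nrow(b)])
  if (any(bad)) {
    abort(paste(
      "overlapping blocks in read(s):",
      paste(unique(b$read_id[bad]), collapse = ", ")
    ))
  }
  tibble(
    read_id = b$read_id,
    chrom = b$chrom,
    strand = b$strand,
    block_rank = as.integer(rank),
    start = as.integer(b$start),
    end = as.integer(b$end),
    read_start_5p = as.integer(if_else(
      b$strand == "+",
      rep(b$start[first_i], lens),
      rep(b$end[last] - 1L, lens)
    ))
  )
}

#' Assign each read to a gene by maximal overlap
#'
#' Candidate genes are all genes whose span overlaps any aligned block
#' (strand-agnostic, so antisense reads stay assignable). The read is
#' assigned to the candidate with the largest overlap in aligned bp, provided
#' at least `min_frac` of the read's aligned bases fall inside that gene's
#' span; an exact tie between best candidates leaves the read unassigned.
#'
#' @param reads A spliced-read tibble from [read_spliced_reads()].
#' @param ann A [gene_annotation].
#' @param min_frac Minimum fraction of aligned bp inside the gene span
#'   (default 0.5).
#' @return A tibble (read_id, gene_id) with `NA` gene_id for unassignable
#'   reads; one row per read.
#' @export
assign_reads_to_genes <- function(reads, ann, min_frac = 0.5) {
  stopifnot(inherits(ann, "gene_annotation"))
  block_gr <- as_granges0(reads)
  GenomicRanges::strand(block_gr) <- "*"
  gene_gr <- as_granges0(ann$genes, id_col = "gene_id")
  GenomicRanges::strand(gene_gr) <- "*"

  hits <- GenomicRanges::findOverlaps(block_gr, gene_gr)
  ov_width <- GenomicRanges::width(GenomicRanges::pintersect(
    block_gr[queryHits(hits)], gene_gr[subjectHits(hits)]
  ))
  rid <- reads$read_id[queryHits(hits)]
  gid <- S4Vectors::mcols(gene_gr)$id[subjectHits(hits)]
  key <- paste(rid, gid, sep = "\r")
  agg <- rowsum(ov_width, key)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  per_pair <- tibble(
    read_id = vapply(parts, `[[`, character(1), 1L),
    gene_id = vapply(parts, `[[`, character(1), 2L),
    ov = agg[, 1]
  )
  aligned_bp <- tibble(
    read_id = rownames(rowsum(reads$end - reads$start, reads$read_id)),
    aligned = rowsum(reads$end - reads$start, reads$read_id)[, 1]
  )

  # best candidate per read; an exact tie for the maximum leaves the read
  # unassigned, as does < min_frac of aligned bp inside the gene span
  pp <- per_pair[order(per_pair$read_id, -per_pair$ov), ]
  is_first <- !duplicated(pp$read_id)
  top <- pp[is_first, ]
  runner_ov <- rep(NA_real_, nrow(top))
  second_idx <- which(is_first) + 1L
  has_second <- second_idx <= nrow(pp) &
    pp$read_id[pmin(second_idx, nrow(pp))] == top$read_id
  runner_ov[has_second] <- pp$ov[second_idx[has_second]]
  best <- top |>
    left_join(aligned_bp, by = "read_id") |>
    mutate(gene_id = if_else(
      (is.na(runner_ov) | .env$runner_ov < .data$ov) &
        .data$ov / .data$aligned >= min_frac,
      .data$gene_id, NA_character_
    )) |>
    select("read_id", "gene_id")

  tibble(read_id = unique(reads$read_id)) |>
    left_join(best, by = "read_id")
}

#' Classify assigned reads: TSS class, antisense, intron retention
#'
#' Per assigned read:
#' * `antisense` - read strand differs from the gene strand.
#' * `tss_conventional` (sense reads only) - the read's 5' start is at or 5'
#'   of the start of annotated exon 1 plus `tss_tolerance`, in gene
#'   orientation; reads beginning after the start of exon 1 are
#'   nonconventional (internal initiation).
#' * `tss_in_intron` - nonconventional and the 5' start falls inside an
#'   annotated intron.
#' * `retained_introns` - annotated introns entirely contained in a single
#'   aligned block (the intron was not spliced out); `n_retained` counts
#'   them.
#'
#' @param reads A spliced-read tibble.
#' @param ann A [gene_annotation].
#' @param assignments Optional precomputed output of
#'   [assign_reads_to_genes()]; computed if missing.
#' @param tss_tolerance Allowed bp downstream of the exon-1 start for a read
#'   to still count as conventional (default 0).
#' @return A tibble with one row per assigned read: read_id, gene_id, strand,
#'   antisense, tss_conventional (NA for antisense reads), tss_in_intron,
#'   n_retained, retained_introns (list of intron ranks).
#' @export
classify_reads <- function(reads, ann, assignments = NULL, tss_tolerance = 0) {
  stopifnot(inherits(ann, "gene_annotation"))
  if (tss_tolerance < 0) abort("tss_tolerance must be >= 0")
  if (is.null(assignments)) {
    assignments <- assign_reads_to_genes(reads, ann)
  }
  assigned <- assignments |> filter(!is.na(.data$gene_id))
  if (nrow(assigned) == 0) {
    return(tibble(
      read_id = character(), gene_id = character(), strand = character(),
      antisense = logical(), tss_conventional = logical(),
      tss_in_intron = logical(), n_retained = integer(),
      retained_introns = list()
    ))
  }

  read_info <- reads |>
    distinct(.data$read_id, .data$chrom, .data$strand, .data$read_start_5p) |>
    inner_join(assigned, by = "read_id") |>
    inner_join(
      ann$genes |>
        select("gene_id",
          gene_chrom = "chrom", gene_strand = "strand",
          gene_start = "start", gene_end = "end"
        ),
      by = "gene_id"
    )
  if (any(read_info$chrom != read_info$gene_chrom)) {
    abort("read assigned to a gene on a different chromosome")
  }

  exon1 <- ann$exons |>
    filter(.data$exon_rank == 1L) |>
    select("gene_id", e1_start = "start", e1_end = "end")
  read_info <- read_info |>
    inner_join(exon1, by = "gene_id") |>
    mutate(
      antisense = .data$strand != .data$gene_strand,
      # exon-1 start in gene orientation: left edge on +, right edge - 1 on -
      tss_conventional = if_else(
        .data$antisense, NA,
        if_else(
          .data$gene_strand == "+",
          .data$read_start_5p <= .data$e1_start + tss_tolerance,
          .data$read_start_5p >= .data$e1_end - 1L - tss_tolerance
        )
      )
    )

  # 5' start inside an annotated intron of the assigned gene
  starts <- read_info |> filter(!.data$antisense, !.data$tss_conventional)
  in_intron <- if (nrow(starts) > 0 && nrow(ann$introns) > 0) {
    s_gr <- GenomicRanges::GRanges(
      starts$chrom,
      IRanges::IRanges(starts$read_start_5p + 1L, starts$read_start_5p + 1L)
    )
    i_gr <- as_granges0(ann$introns, id_col = "gene_id")
    GenomicRanges::strand(i_gr) <- "*"
    hits <- GenomicRanges::findOverlaps(s_gr, i_gr)
    ok <- starts$gene_id[queryHits(hits)] ==
      S4Vectors::mcols(i_gr)$id[subjectHits(hits)]
    starts$read_id[unique(queryHits(hits)[ok])]
  } else {
    character()
  }

  # intron retention: intron entirely within one aligned block of the read
  blocks_assigned <- reads |> semi_join(assigned, by = "read_id")
  retained <- if (nrow(ann$introns) > 0 && nrow(blocks_assigned) > 0) {
    b_gr <- as_granges0(blocks_assigned)
    GenomicRanges::strand(b_gr) <- "*"
    i_gr <- as_granges0(ann$introns, id_col = "gene_id")
    GenomicRanges::strand(i_gr) <- "*"
    hits <- GenomicRanges::findOverlaps(i_gr, b_gr, type = "within")
    cand <- tibble(
      gene_id = S4Vectors::mcols(i_gr)$id[queryHits(hits)],
      intron_rank = ann$introns$intron_rank[queryHits(hits)],
      read_id = blocks_assigned$read_id[subjectHits(hits)]
    ) |>
      inner_join(assigned, by = c("read_id", "gene_id")) |>
      distinct(.data$read_id, .data$intron_rank)
    cand
  } else {
    tibble(read_id = character(), intron_rank = integer())
  }
  retained_by_read <- retained |>
    group_by(.data$read_id) |>
    summarise(
      retained_introns = list(sort(.data$intron_rank)),
      n_retained = n(),
      .groups = "drop"
    )

  read_info |>
    left_join(retained_by_read, by = "read_id") |>
    mutate(
      tss_in_intron = !is.na(.data$tss_conventional) &
        !.data$tss_conventional & .data$read_id %in% in_intron,
      n_retained = tidyr::replace_na(.data$n_retained, 0L),
      retained_introns = {
        ri <- .data$retained_introns
        if (is.null(ri)) ri <- vector("list", dplyr::n())
        ri[vapply(ri, is.null, logical(1))] <- list(integer())
        ri
      }
    ) |>
    select(
      "read_id", "gene_id", "strand", "antisense", "tss_conventional",
      "tss_in_intron", "n_retained", "retained_introns"
    )
}

#' Per-gene long-read transcript-integrity metrics
#'
#' Aggregates per-read calls into the three per-gene proportions:
#' * `prop_conventional_tss` = conventional / sense reads;
#' * `prop_antisense` = antisense / all assigned reads;
#' * `prop_intron_retained` = sense reads retaining >= 1 intron / sense reads
#'   (genes without introns are excluded from this metric).
#'
#' A proportion is `NA` when its denominator is below `min_reads`.
#' `expression_proxy` is the total number of assigned reads.
#'
#' @param calls Output of [classify_reads()].
#' @param ann A [gene_annotation].
#' @param min_reads Minimum denominator for a proportion (default 5).
#' @return A tibble with one row per gene that received >= 1 read, plus
#'   favorable/eligible count columns for downstream GLMs.
#' @export
gene_longread_metrics <- function(calls, ann, min_reads = 5) {
  stopifnot(inherits(ann, "gene_annotation"))
  agg <- calls |>
    group_by(.data$gene_id) |>
    summarise(
      n_reads = n(),
      n_sense = sum(!.data$antisense),
      n_antisense = sum(.data$antisense),
      n_conventional = sum(.data$tss_conventional, na.rm = TRUE),
      n_tss_in_intron = sum(.data$tss_in_intron, na.rm = TRUE),
      n_retaining = sum(!.data$antisense & .data$n_retained > 0),
      .groups = "drop"
    )
  agg |>
    inner_join(
      ann$genes |> select("gene_id", gene_length = "length", "n_exons"),
      by = "gene_id"
    ) |>
    mutate(
      has_introns = .data$n_exons > 1L,
      prop_conventional_tss = if_else(
        .data$n_sense >= min_reads,
        .data$n_conventional / .data$n_sense, NA_real_
      ),
      prop_antisense = if_else(
        .data$n_reads >= min_reads,
        .data$n_antisense / .data$n_reads, NA_real_
      ),
      prop_intron_retained = if_else(
        .data$has_introns & .data$n_sense >= min_reads,
        .data$n_retaining / .data$n_sense, NA_real_
      ),
      expression_proxy = .data$n_reads
    ) |>
    select(-"has_introns", -"n_exons")
}
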