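#' Build a gene annotation object from an exon table
#'
#' A `gene_annotation` is the coordinate backbone used by every other stage:
#' per gene, a strand-aware canonical exon/intron structure. Exons are ranked
#' in transcriptional (5'->3') order, so for a minus-strand gene exon 1 is the
#' rightmost exon in chromosome coordinates. Introns are derived as the gaps
#' between consecutive exons.
#'
#' @param exons A data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (one exon per row, 0-based half-open coordinates).
#' @return An object of class `gene_annotation`: a list of three tibbles,
#'   `genes` (gene_id, chrom, start, end, strand, n_exons, length),
#'   `exons` (gene_id, exon_rank, chrom, start, end, strand) and
#'   `introns` (gene_id, intron_rank, chrom, start, end, strand).
#' @examples
#' ex <- tibble::tibble(
#'   gene_id = "g1", chrom = "chr1",
#'   start = c(100, 300), end = c(200, 400), strand = "+"
#' )
#' ann <- gene_annotation(ex)
#' ann$introns
#' @export
gene_annotation <- function(exons) {
  exons <- as_tibble(exons)
  req <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(req %in% names(exons))) {
    abort(paste("exon table must have columns:", paste(req, collapse = ", ")))
  }
  if (any(exons$start >= exons$end) || any(exons$start < 0)) {
    abort("exon intervals must satisfy 0 <= start < end")
  }
  if (!all(exons$strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-'")
  }

  exons <- exons |>
    group_by(.data$gene_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(
      .overlap = .data$start < dplyr::lag(.data$end, default = -1L)
    ) |>
    ungroup()
  if (any(exons$.overlap)) {
    abort(paste(
      "overlapping exons in gene(s):",
      paste(unique(exons$gene_id[exons$.overlap]), collapse = ", ")
    ))
  }

  # rank 5'->3': ascending start on +, descending on -
  exons <- exons |>
    group_by(.data$gene_id) |>
    mutate(exon_rank = if (first(.data$strand) == "+") {
      row_number()
    } else {
      n() - row_number() + 1L
    }) |>
    ungroup() |>
    select("gene_id", "exon_rank", "chrom", "start", "end", "strand") |>
    arrange(.data$gene_id, .data$exon_rank)

  genes <- exons |>
    group_by(.data$gene_id) |>
    summarise(
      chrom = first(.data$chrom),
      start = min(.data$start),
      end = max(.data$end),
      strand = first(.data$strand),
      n_exons = n(),
      .groups = "drop"
    ) |>
    mutate(length = .data$end - .data$start)

  introns <- derive_introns(exons)

  structure(
    list(genes = genes, exons = exons, introns = introns),
    class = "gene_annotation"
  )
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(
    "<gene_annotation>", nrow(x$genes), "genes,",
    nrow(x$exons), "exons,", nrow(x$introns), "introns\n"
  )
  invisible(x)
}

#' @method as_tibble gene_annotation
#' @export
as_tibble.gene_annotation <- function(x, ...) x$genes

#' Derive introns from a ranked exon table
#'
#' Intron i spans the gap between exon i and exon i+1 in transcriptional
#' order; single-exon genes contribute no introns.
#'
#' @param exons A tibble with `gene_id`, `exon_rank`, `chrom`, `start`, `end`,
#'   `strand` (0-based half-open; rank 1 is the 5'-most exon).
#' @return A tibble of introns with `intron_rank` in transcriptional order.
#' @export
derive_introns <- function(exons) {
  exons <- as_tibble(exons)
  ordered <- exons |> arrange(.data$gene_id, .data$exon_rank)
  bad <- ordered |>
    group_by(.data$gene_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    summarise(ov = any(.data$start < dplyr::lag(.data$end, default = -1L)),
              .groups = "drop")
  if (any(bad$ov)) abort("overlapping exons")

  ordered |>
    group_by(.data$gene_id) |>
    mutate(
      nxt_start = dplyr::lead(.data$start),
      nxt_end = dplyr::lead(.data$end)
    ) |>
    filter(!is.na(.data$nxt_start)) |>
    mutate(
      intron_rank = row_number(),
      i_start = if_else(.data$strand == "+", .data$end, .data$nxt_end),
      i_end = if_else(.data$strand == "+", .data$nxt_start, .data$start)
    ) |>
    ungroup() |>
    select(
      "gene_id", "intron_rank", "chrom",
      start = "i_start", end = "i_end", "strand"
    )
}

#' Pick the canonical transcript among a gene's isoforms
#'
#' The canonical transcript is the one with the greatest summed exon length;
#' ties break to the lexicographically smallest transcript id.
#'
#' @param transcripts A data frame of exons with columns `transcript_id`,
#'   `start`, `end` (one row per exon, any coordinate convention).
#' @return The rows of the chosen transcript.
#' @export
select_canonical <- function(transcripts) {
  transcripts <- as_tibble(transcripts)
  if (nrow(transcripts) == 0) abort("no transcripts supplied")
  best <- transcripts |>
    group_by(.data$transcript_id) |>
    summarise(exonic = sum(.data$end - .data$start), .groups = "drop") |>
    arrange(dplyr::desc(.data$exonic), .data$transcript_id) |>
    slice(1)
  transcripts |> filter(.data$transcript_id == best$transcript_id)
}

#' Read a GFF3 gene annotation into canonical gene models
#'
#' Parses gene/mRNA/exon features (via rtracklayer), resolves each exon to its
#' parent gene through the mRNA `Parent` attributes, selects one canonical
#' transcript per gene (longest summed exon length, ties to the smallest
#' transcript id; or the union of all isoform exons with
#' `isoform = "union"`), and converts GFF3 1-based closed coordinates to the
#' 0-based half-open convention used internally. Genes whose transcripts have
#' no exon children are skipped with a warning.
#'
#' @param path Path to a GFF3 file.
#' @param isoform `"canonical"` (default) or `"union"`.
#' @return A [gene_annotation] object.
#' @export
read_gene_annotation <- function(path, isoform = c("canonical", "union")) {
  isoform <- match.arg(isoform)
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) abort(paste("malformed GFF3:", conditionMessage(e)))
  )
  df <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L, # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(S4Vectors::mcols(gr)$type),
    id = as.character(S4Vectors::mcols(gr)$ID),
    parent = vapply(
      as.list(S4Vectors::mcols(gr)$Parent),
      function(p) if (length(p)) p[[1]] else NA_character_,
      character(1)
    )
  )

  genes <- df |> filter(.data$type == "gene")
  mrnas <- df |> filter(.data$type %in% c("mRNA", "transcript"))
  exons <- df |> filter(.data$type == "exon")
  if (nrow(genes) == 0) abort("GFF3 contains no gene features")

  tx2gene <- setNames(mrnas$parent, mrnas$id)
  exons <- exons |>
    mutate(
      transcript_id = .data$parent,
      gene_id = unname(tx2gene[.data$parent])
    )
  orphans <- is.na(exons$gene_id) | !(exons$gene_id %in% genes$id)
  if (any(orphans)) {
    warn(paste(sum(orphans), "exon(s) without resolvable parent gene; skipped"))
    exons <- exons[!orphans, ]
  }

  chosen <- if (isoform == "canonical") {
    exons |>
      group_by(.data$gene_id) |>
      dplyr::group_modify(~ select_canonical(.x)) |>
      ungroup()
  } else {
    # union mode: merge overlapping exon intervals across isoforms
    exons |>
      group_by(.data$gene_id, .data$chrom, .data$strand) |>
      arrange(.data$start, .by_group = TRUE) |>
      mutate(grp = cumsum(.data$start > cummax(dplyr::lag(.data$end, default = -1L)))) |>
      group_by(.data$gene_id, .data$chrom, .data$strand, .data$grp) |>
      summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  }

  no_exons <- setdiff(genes$id, chosen$gene_id)
  if (length(no_exons) > 0) {
    warn(paste(
      "gene(s) with no exon-bearing transcript skipped:",
      paste(head(no_exons, 5), collapse = ", ")
    ))
  }
  if (nrow(chosen) == 0) abort("no gene with exons found in GFF3")

  gene_annotation(
    chosen |> select("gene_id", "chrom", "start", "end", "strand")
  )
}

#' Write a gene annotation back to GFF3
#'
#' Emits one gene, one mRNA (`<gene_id>.1`) and the canonical exons per gene,
#' converting back to 1-based closed GFF3 coordinates. Re-reading the file
#' with [read_gene_annotation()] reproduces the same models.
#'
#' @param ann A [gene_annotation].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "gene_annotation"))
  g <- ann$genes
  e <- ann$exons |> arrange(.data$gene_id, .data$start)

  feat <- bind_rows(
    g |> mutate(type = "gene", id = .data$gene_id, parent = NA_character_),
    g |> mutate(
      type = "mRNA", id = paste0(.data$gene_id, ".1"),
      parent = .data$gene_id
    ),
    e |> mutate(
      type = "exon", id = NA_character_,
      parent = paste0(.data$gene_id, ".1")
    )
  ) |>
    arrange(.data$chrom, .data$start, factor(.data$type, c("gene", "mRNA", "exon")))

  gr <- GenomicRanges::GRanges(
    feat$chrom,
    IRanges::IRanges(feat$start + 1L, feat$end),
    strand = feat$strand
  )
  S4Vectors::mcols(gr)$type <- feat$type
  S4Vectors::mcols(gr)$ID <- feat$id
  S4Vectors::mcols(gr)$Parent <- IRanges::CharacterList(
    lapply(feat$parent, function(p) if (is.na(p)) character() else p)
  )
  rtracklayer::export(gr, path, format = "gff3")
  # drop volatile comment lines so identical inputs give byte-identical files
  lines <- readLines(path)
  keep <- !grepl("^##(date|source-version)", lines)
  writeLines(lines[keep], path)
  invisible(path)
}

#' Gene-level summary table of an annotation
#'
#' @param ann A [gene_annotation].
#' @return A tibble (gene_id, chrom, start, end, strand, n_exons, length).
#' @export
gene_table <- function(ann) {
  stopifnot(inherits(ann, "gene_annotation"))
  ann$genes
}
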