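#' Read a Bismark-style cytosine report
#'
#' Expects the tab-separated columns chromosome, 1-based position, strand,
#' count methylated, count unmethylated, context (CG/CHG/CHH) and optionally
#' the trinucleotide. Positions are converted to 0-based; sites with total
#' coverage below `min_coverage` are dropped.
#'
#' @param path Path to the report (TSV, no header).
#' @param min_coverage Minimum total read count to keep a site (default 3).
#' @return A tibble (chrom, pos, strand, context, meth_reads, unmeth_reads).
#' @export
read_cytosine_report <- function(path, min_coverage = 3) {
  raw <- readr::read_tsv(
    path,
    col_names = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (ncol(raw) < 6) abort("cytosine report needs at least 6 columns")
  out <- tibble(
    chrom = raw[[1]],
    pos = suppressWarnings(as.integer(raw[[2]])) - 1L,
    strand = raw[[3]],
    meth_reads = suppressWarnings(as.integer(raw[[4]])),
    unmeth_reads = suppressWarnings(as.integer(raw[[5]])),
    context = raw[[6]]
  )
  if (anyNA(out$pos) || anyNA(out$meth_reads) || anyNA(out$unmeth_reads)) {
    abort("non-integer position or count in cytosine report")
  }
  bad_ctx <- setdiff(unique(out$context), c("CG", "CHG", "CHH"))
  if (length(bad_ctx) > 0) {
    abort(paste("unknown methylation context:", paste(bad_ctx, collapse = ", ")))
  }
  out |>
    filter(.data$meth_reads + .data$unmeth_reads >= min_coverage) |>
    select("chrom", "pos", "strand", "context", "meth_reads", "unmeth_reads")
}

#' Call per-site methylation status against the non-conversion error rate
#'
#' A cytosine site is called methylated when its methylated-read count is
#' larger than expected from bisulfite non-conversion alone: the upper-tail
#' exact binomial probability P(X >= meth_reads | n = coverage, p =
#' error_rate) is computed for every site and Benjamini-Hochberg adjusted
#' across all sites; sites with adjusted p below `alpha` are called
#' methylated.
#'
#' @param sites A tibble as returned by [read_cytosine_report()].
#' @param error_rate Bisulfite non-conversion rate, in (0,1) (default 0.005).
#' @param alpha FDR level for the site-level call (default 0.05).
#' @return `sites` with added columns `p_site`, `q_site`, `methylated`.
#' @export
call_site_methylation <- function(sites, error_rate = 0.005, alpha = 0.05) {
  sites <- as_tibble(sites)
  if (error_rate <= 0 || error_rate >= 1) abort("error_rate must be in (0,1)")
  total <- sites$meth_reads + sites$unmeth_reads
  if (any(total == 0)) abort("site with zero total reads")
  p <- pbinom(sites$meth_reads - 1L, total, error_rate, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  sites |>
    mutate(p_site = p, q_site = q, methylated = q < alpha)
}

#' Summarise site calls into per-gene, per-context methylation profiles
#'
#' Sites are matched to genes by position within the gene span (strand is
#' ignored: both strands of a symmetric context report against the gene).
#'
#' @param sites Output of [call_site_methylation()].
#' @param ann A [gene_annotation].
#' @return A tibble (gene_id, context, n_sites, n_meth), one row per gene and
#'   context (contexts with no covered sites get zeros).
#' @export
summarize_gene_methylation <- function(sites, ann) {
  stopifnot(inherits(ann, "gene_annotation"))
  if (!"methylated" %in% names(sites)) {
    abort("sites must carry a 'methylated' column; run call_site_methylation()")
  }
  site_gr <- GenomicRanges::GRanges(
    sites$chrom, IRanges::IRanges(sites$pos + 1L, sites$pos + 1L), strand = "*"
  )
  gene_gr <- as_granges0(ann$genes, id_col = "gene_id")
  GenomicRanges::strand(gene_gr) <- "*"
  hits <- GenomicRanges::findOverlaps(site_gr, gene_gr)

  matched <- tibble(
    gene_id = S4Vectors::mcols(gene_gr)$id[subjectHits(hits)],
    context = sites$context[queryHits(hits)],
    methylated = sites$methylated[queryHits(hits)]
  )
  counts <- matched |>
    group_by(.data$gene_id, .data$context) |>
    summarise(
      n_sites = n(),
      n_meth = sum(.data$methylated),
      .groups = "drop"
    )

  tidyr::expand_grid(
    gene_id = ann$genes$gene_id,
    context = c("CG", "CHG", "CHH")
  ) |>
    left_join(counts, by = c("gene_id", "context")) |>
    mutate(
      n_sites = tidyr::replace_na(.data$n_sites, 0L),
      n_meth = tidyr::replace_na(.data$n_meth, 0L)
    )
}

#' Genic-average (background) methylation rates per context
#'
#' The background rate of a context is the pooled fraction of methylated
#' sites across all genes: sum(n_meth) / sum(n_sites). It is the null rate
#' of the gene-level binomial classification test.
#'
#' @param profiles Output of [summarize_gene_methylation()].
#' @return A tibble (context, p_bg).
#' @export
compute_background <- function(profiles) {
  bg <- profiles |>
    group_by(.data$context) |>
    summarise(
      total_sites = sum(.data$n_sites),
      p_bg = sum(.data$n_meth) / sum(.data$n_sites),
      .groups = "drop"
    )
  empty <- bg$context[bg$total_sites == 0]
  if (length(empty) > 0) {
    abort(paste(
      "no covered sites genome-wide in context:",
      paste(empty, collapse = ", ")
    ))
  }
  bg |> select("context", "p_bg")
}

#' Classify genes as gbM, UM, teM or undetermined
#'
#' Implements the statistical definition of gene body methylation: per gene
#' and context, exact binomial upper- and lower-tail p-values of the
#' methylated-site count against the genic-average rate, Benjamini-Hochberg
#' adjusted across genes within each context and tail. Labels:
#'
#' * `gbM` - CG upper tail significant, and neither CHG nor CHH upper tail
#'   significant (CG-only body methylation). In `strict` mode gbM
#'   additionally requires CHG and CHH lower-tail significance (literally
#'   "less methylated than the genic average" in non-CG contexts).
#' * `teM` - CHG or CHH upper tail significant (TE-like methylation), taking
#'   precedence over gbM.
#' * `UM` - no upper tail significant in any context and CG lower tail
#'   significant (actively less CG-methylated than the genic average).
#' * `undetermined` - anything else, including genes with fewer than
#'   `min_sites` covered CG sites (`reason` column says why).
#'
#' @param profiles Output of [summarize_gene_methylation()].
#' @param background Output of [compute_background()].
#' @param alpha FDR level (default 0.05).
#' @param min_sites Minimum covered CG sites for a gene to be classifiable
#'   (default 20).
#' @param strict Require CHG and CHH lower-tail significance for gbM
#'   (default FALSE).
#' @return A tibble with one row per gene: per-context site counts, per-tail
#'   q-values, `class_label` and `reason`.
#' @export
classify_genes <- function(profiles, background, alpha = 0.05,
                           min_sites = 20, strict = FALSE) {
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0,1)")
  long <- profiles |>
    inner_join(background, by = "context") |>
    mutate(
      p_up = pbinom(.data$n_meth - 1L, .data$n_sites, .data$p_bg,
        lower.tail = FALSE
      ),
      p_lo = pbinom(.data$n_meth, .data$n_sites, .data$p_bg),
      # untestable (zero-site) gene-contexts get p = 1, and q adjusted only
      # across tested genes
      p_up = if_else(.data$n_sites > 0, .data$p_up, 1),
      p_lo = if_else(.data$n_sites > 0, .data$p_lo, 1)
    ) |>
    group_by(.data$context) |>
    mutate(
      q_up = if_else(
        .data$n_sites > 0,
        p.adjust(if_else(.data$n_sites > 0, .data$p_up, NA_real_), "BH"),
        1
      ),
      q_lo = if_else(
        .data$n_sites > 0,
        p.adjust(if_else(.data$n_sites > 0, .data$p_lo, NA_real_), "BH"),
        1
      )
    ) |>
    ungroup()

  wide <- long |>
    select("gene_id", "context", "n_sites", "n_meth", "q_up", "q_lo") |>
    tidyr::pivot_wider(
      names_from = "context",
      values_from = c("n_sites", "n_meth", "q_up", "q_lo"),
      names_glue = "{.value}_{tolower(context)}"
    )

  wide |>
    mutate(
      sig_up_cg = .data$q_up_cg < alpha,
      sig_up_chg = .data$q_up_chg < alpha,
      sig_up_chh = .data$q_up_chh < alpha,
      sig_lo_cg = .data$q_lo_cg < alpha,
      sig_lo_chg = .data$q_lo_chg < alpha,
      sig_lo_chh = .data$q_lo_chh < alpha,
      eligible = .data$n_sites_cg >= min_sites,
      gbm_ok = .data$sig_up_cg & !.data$sig_up_chg & !.data$sig_up_chh &
        (!strict | (.data$sig_lo_chg & .data$sig_lo_chh)),
      class_label = case_when(
        !eligible ~ "undetermined",
        .data$sig_up_chg | .data$sig_up_chh ~ "teM",
        gbm_ok ~ "gbM",
        !.data$sig_up_cg & .data$sig_lo_cg ~ "UM",
        TRUE ~ "undetermined"
      ),
      reason = case_when(
        !eligible ~ "too_few_cg_sites",
        class_label == "undetermined" ~ "ambiguous_signal",
        TRUE ~ NA_character_
      )
    ) |>
    select(-dplyr::starts_with("sig_"), -"eligible", -"gbm_ok")
}

#' One-call gene classification from files
#'
#' Convenience wrapper: read a cytosine report, call sites, summarise per
#' gene, estimate the background and classify.
#'
#' @param report_path Path to a Bismark-style cytosine report.
#' @param ann A [gene_annotation].
#' @param min_coverage,error_rate,alpha,min_sites,strict Passed to the
#'   component steps.
#' @return A list with `classification` (tibble from [classify_genes()]) and
#'   `background` (tibble from [compute_background()]).
#' @export
classify_methylome <- function(report_path, ann, min_coverage = 3,
                               error_rate = 0.005, alpha = 0.05,
                               min_sites = 20, strict = FALSE) {
  sites <- read_cytosine_report(report_path, min_coverage = min_coverage)
  sites <- call_site_methylation(sites, error_rate = error_rate, alpha = alpha)
  profiles <- summarize_gene_methylation(sites, ann)
  background <- compute_background(profiles)
  classification <- classify_genes(
    profiles, background,
    alpha = alpha, min_sites = min_sites, strict = strict
  )
  list(classification = classification, background = background)
}
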