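#' Run the long-read transcript-integrity analysis
#'
#' Orchestrates the full long-read arm: classify genes from the bisulfite
#' cytosine report, assign and classify the spliced long reads, aggregate
#' per-gene metrics, and compare gbM vs UM genes on each of the three
#' metrics (conventional-TSS proportion, antisense proportion,
#' intron-retention proportion) with a two-sided Wilcoxon test and the
#' covariate-adjusted binomial GLM.
#'
#' @param gff3 Path to the GFF3 annotation.
#' @param cytosine_report Path to the Bismark-style cytosine report.
#' @param long_reads Path to the BED12 spliced-read alignments.
#' @param alpha,min_coverage,min_sites,error_rate Methylation-classifier
#'   thresholds, see [classify_genes()].
#' @param tss_tolerance,min_reads Long-read thresholds, see
#'   [classify_reads()] and [gene_longread_metrics()].
#' @return An object of class `gbmti_report`: a list with `classification`,
#'   `background`, `metrics` (per-gene table joined with class labels),
#'   `comparisons` (one summary row per metric), `fits` (named list of
#'   `prop_glm` objects) and `params`.
#' @export
run_longread_analysis <- function(gff3, cytosine_report, long_reads,
                                  alpha = 0.05, min_coverage = 3,
                                  min_sites = 20, error_rate = 0.005,
                                  tss_tolerance = 0, min_reads = 5) {
  for (f in c(gff3, cytosine_report, long_reads)) {
    if (!file.exists(f)) abort(paste("input file not found:", f))
  }
  ann <- read_gene_annotation(gff3)
  meth <- classify_methylome(
    cytosine_report, ann,
    min_coverage = min_coverage, error_rate = error_rate,
    alpha = alpha, min_sites = min_sites
  )
  reads <- read_spliced_reads(long_reads)
  calls <- classify_reads(reads, ann, tss_tolerance = tss_tolerance)
  metrics <- gene_longread_metrics(calls, ann, min_reads = min_reads)

  labelled <- metrics |>
    inner_join(
      meth$classification |> select("gene_id", "class_label"),
      by = "gene_id"
    )
  n_class <- labelled |>
    filter(.data$class_label %in% c("gbM", "UM")) |>
    count(.data$class_label)
  for (cl in c("gbM", "UM")) {
    if (!cl %in% n_class$class_label) {
      abort(paste0(
        "no ", cl, " genes left after classification and read filtering; ",
        "cannot compare groups"
      ))
    }
  }

  spec_tbl <- tibble(
    metric = c("prop_conventional_tss", "prop_antisense", "prop_intron_retained"),
    favorable = c("n_conventional", "n_antisense", "n_retaining"),
    eligible = c("n_sense", "n_reads", "n_sense")
  )
  comps <- purrr::pmap(spec_tbl, function(metric, favorable, eligible) {
    df <- labelled |>
      mutate(
        favorable_count = .data[[favorable]],
        eligible_count = .data[[eligible]]
      )
    compare_groups(df, metric, alternative = "two_sided")
  })
  names(comps) <- spec_tbl$metric

  structure(
    list(
      classification = meth$classification,
      background = meth$background,
      metrics = labelled,
      comparisons = purrr::map(comps, "summary") |> bind_rows(),
      fits = purrr::map(comps, "fit"),
      params = list(
        alpha = alpha, min_coverage = min_coverage, min_sites = min_sites,
        error_rate = error_rate, tss_tolerance = tss_tolerance,
        min_reads = min_reads
      )
    ),
    class = "gbmti_report"
  )
}

#' Run the short-read WT-vs-mutant coverage analysis
#'
#' Computes exon3/exon1 coverage ratios and intron RPKM per gene for each
#' condition (e.g. WT and a methylation mutant) and compares gbM vs UM genes
#' within each condition with one-sided Wilcoxon tests (alternative: gbM
#' lower). Methylation labels are always taken from the reference (WT)
#' methylome and propagated to every condition, so mutant genes are grouped
#' by their WT label — the design that distinguishes methylation effects from
#' stable gene properties.
#'
#' @param gff3 Path to the GFF3 annotation.
#' @param cytosine_report Path to the reference (WT) cytosine report used for
#'   classification.
#' @param conditions Named list; each element is either a BED path or a list
#'   with `reads` (BED path) and optional `library_size`.
#' @param alpha,min_coverage,min_sites,error_rate Classifier thresholds.
#' @param strandedness,min_denominator Coverage options, see
#'   [gene_coverage_metrics()].
#' @return An object of class `gbmti_report` with `classification`,
#'   `metrics` (per-gene per-condition), and `comparisons` (one row per
#'   condition and metric).
#' @export
run_shortread_analysis <- function(gff3, cytosine_report, conditions,
                                   alpha = 0.05, min_coverage = 3,
                                   min_sites = 20, error_rate = 0.005,
                                   strandedness = "unstranded",
                                   min_denominator = 1) {
  if (is.null(names(conditions)) || any(names(conditions) == "")) {
    abort("conditions must be a named list (e.g. WT, mutant)")
  }
  for (f in c(gff3, cytosine_report)) {
    if (!file.exists(f)) abort(paste("input file not found:", f))
  }
  ann <- read_gene_annotation(gff3)
  meth <- classify_methylome(
    cytosine_report, ann,
    min_coverage = min_coverage, error_rate = error_rate,
    alpha = alpha, min_sites = min_sites
  )
  labels <- meth$classification |> select("gene_id", "class_label")
  if (sum(labels$class_label == "gbM") == 0 ||
    sum(labels$class_label == "UM") == 0) {
    abort("reference methylome classification yields an empty gbM or UM group")
  }

  per_condition <- purrr::imap(conditions, function(cond, cond_name) {
    if (!is.list(cond)) cond <- list(reads = cond)
    if (!file.exists(cond$reads)) {
      abort(paste0("missing reads for condition '", cond_name, "': ", cond$reads))
    }
    reads <- read_read_intervals(cond$reads)
    lib <- cond$library_size %||% nrow(reads)
    if (nrow(reads) > lib) {
      abort(paste0(
        "condition '", cond_name, "': read count (", nrow(reads),
        ") exceeds declared library_size (", lib, ")"
      ))
    }
    gene_coverage_metrics(
      reads, ann,
      library_size = lib, strandedness = strandedness,
      min_denominator = min_denominator
    ) |>
      mutate(condition = cond_name)
  })
  metrics <- bind_rows(per_condition) |>
    inner_join(labels, by = "gene_id")

  comparisons <- metrics |>
    tidyr::pivot_longer(
      c("exon3_exon1_ratio", "intron_rpkm"),
      names_to = "metric", values_to = "value"
    ) |>
    filter(!is.na(.data$value), .data$class_label %in% c("gbM", "UM")) |>
    group_by(.data$condition, .data$metric) |>
    dplyr::group_modify(function(d, key) {
      compare_groups(
        d |> rename(!!key$metric := "value"),
        key$metric,
        alternative = "gbm_less", glm_adjust = FALSE
      )$summary |>
        select(-"metric") # the group key already carries it
    }) |>
    ungroup() |>
    dplyr::relocate("condition")

  structure(
    list(
      classification = meth$classification,
      background = meth$background,
      metrics = metrics,
      comparisons = comparisons,
      fits = NULL,
      params = list(
        alpha = alpha, min_coverage = min_coverage, min_sites = min_sites,
        error_rate = error_rate, strandedness = strandedness,
        min_denominator = min_denominator
      )
    ),
    class = "gbmti_report"
  )
}

#' @export
print.gbmti_report <- function(x, ...) {
  n_lab <- table(x$classification$class_label)
  cat("<gbmti_report>\n")
  cat(
    " classification:",
    paste(names(n_lab), as.integer(n_lab), collapse = ", "), "\n"
  )
  cat(" comparisons:\n")
  print(as.data.frame(x$comparisons))
  invisible(x)
}

#' @rdname run_longread_analysis
#' @param x A `gbmti_report`.
#' @param ... Unused.
#' @method tidy gbmti_report
#' @export
tidy.gbmti_report <- function(x, ...) x$comparisons

#' Write the tables of a report to a directory
#'
#' Emits `classification.tsv`, `metrics.tsv`, `comparisons.tsv` and a JSON
#' provenance block (`report.json`: parameters, background rates and label
#' counts).
#'
#' @param report A `gbmti_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "gbmti_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(
    classification = file.path(dir, "classification.tsv"),
    metrics = file.path(dir, "metrics.tsv"),
    comparisons = file.path(dir, "comparisons.tsv"),
    json = file.path(dir, "report.json")
  )
  readr::write_tsv(report$classification, paths$classification)
  metrics_flat <- report$metrics |>
    dplyr::select(-dplyr::where(is.list))
  readr::write_tsv(metrics_flat, paths$metrics)
  readr::write_tsv(report$comparisons, paths$comparisons)
  jsonlite::write_json(
    list(
      params = report$params,
      background = report$background,
      label_counts = as.list(table(report$classification$class_label))
    ),
    paths$json,
    auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}
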