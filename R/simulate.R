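#' Default simulation configuration
#'
#' Returns the study conditions emulated by the synthetic-data generator:
#' 2000 multi-exon genes, class priors 0.35 gbM / 0.55 UM / 0.10 teM,
#' class-specific per-context site-methylation rates well separated from the
#' bisulfite non-conversion error, a mean of 20 full-length long reads per
#' gene, and planted class-dependent transcript-integrity parameters at the
#' reported effect sizes: conventional-TSS proportions 0.81 (gbM) vs 0.78
#' (UM), antisense proportions 0.0046 vs 0.016, and intron-retention
#' proportions 0.149 vs 0.106.
#'
#' @param ... Named overrides of any default field.
#' @return A `sim_config` list. Fields of note:
#' * `n_genes`, `class_prior`
#' * `exon_count`, `exon_length`, `intron_length`, `intergenic_gap`:
#'   min/max of the uniform structural distributions (bp)
#' * `site_rates`: per class, per context probability that a cytosine site is
#'   methylated
#' * `site_density`: sites per bp per context; `coverage_mean`: mean bisulfite
#'   coverage; `error_rate`: non-conversion rate; `meth_read_rate`:
#'   methylated-read probability at a truly methylated site
#' * `reads_per_gene_mean`, `reads_per_gene_size`: negative-binomial long-read
#'   counts
#' * `p_conventional`, `p_antisense`, `p_retention`: per class planted
#'   probabilities
#' * `short_reads_per_gene_mean`, `short_read_length`,
#'   `short_internal_weight`, `short_intron_weight`: short-read layer
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_genes = 2000L,
    genes_per_chrom = 500L,
    exon_count = c(3L, 8L),
    exon_length = c(100L, 300L),
    intron_length = c(80L, 200L),
    intergenic_gap = c(500L, 2000L),
    class_prior = c(gbM = 0.35, UM = 0.55, teM = 0.10),
    site_rates = list(
      gbM = c(CG = 0.80, CHG = 0.005, CHH = 0.005),
      UM = c(CG = 0.005, CHG = 0.005, CHH = 0.005),
      teM = c(CG = 0.80, CHG = 0.70, CHH = 0.40)
    ),
    site_density = c(CG = 0.018, CHG = 0.015, CHH = 0.030),
    coverage_mean = 15,
    error_rate = 0.005,
    meth_read_rate = 0.98,
    reads_per_gene_mean = 20,
    reads_per_gene_size = 10,
    p_conventional = c(gbM = 0.81, UM = 0.78, teM = 0.80),
    p_antisense = c(gbM = 0.0046, UM = 0.016, teM = 0.01),
    p_retention = c(gbM = 0.149, UM = 0.106, teM = 0.12),
    p_premrna = c(gbM = 0.05, UM = 0.10, teM = 0.08),
    short_reads_per_gene_mean = 60,
    short_read_length = 75L,
    short_internal_weight = 0.5,
    short_intron_weight = 0.5
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    abort(paste("unknown sim_config field(s):", paste(unknown, collapse = ", ")))
  }
  cfg[names(over)] <- over
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 1) abort("n_genes must be >= 1")
  if (abs(sum(cfg$class_prior) - 1) > 1e-8) abort("class priors must sum to 1")
  probs <- c(
    cfg$class_prior, unlist(cfg$site_rates), cfg$error_rate,
    cfg$meth_read_rate, cfg$p_conventional, cfg$p_antisense, cfg$p_retention,
    cfg$p_premrna, cfg$short_internal_weight, cfg$short_intron_weight
  )
  if (any(probs < 0 | probs > 1)) abort("all probabilities must be in [0,1]")
  for (f in c("p_conventional", "p_antisense", "p_retention", "p_premrna")) {
    if (!all(c("gbM", "UM", "teM") %in% names(cfg[[f]]))) {
      abort(paste(f, "must name gbM, UM and teM"))
    }
  }
  invisible(cfg)
}

#' Simulate a gene annotation with planted methylation classes
#'
#' Genes are laid out non-overlapping along synthetic chromosomes with
#' uniform intergenic gaps; exon counts and exon/intron lengths are uniform
#' within the configured ranges; strands alternate at random. Each gene draws
#' a class from the prior.
#'
#' @param config A [sim_config()].
#' @return A list: `ann` (a [gene_annotation]) and `truth` (tibble gene_id,
#'   class, plus the planted per-gene transcript parameters).
#' @export
simulate_genes <- function(config) {
  n <- config$n_genes
  gene_id <- sprintf("g%05d", seq_len(n))
  n_ex <- sample(seq(config$exon_count[1], config$exon_count[2]), n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  class <- sample(names(config$class_prior), n,
    replace = TRUE, prob = config$class_prior
  )

  # segment lengths: exon, intron, exon, ... per gene
  n_seg <- 2L * n_ex - 1L
  seg_gene <- rep(seq_len(n), n_seg)
  seg_rank <- unlist(lapply(n_seg, seq_len), use.names = FALSE)
  is_exon <- seg_rank %% 2L == 1L
  seg_len <- integer(length(seg_gene))
  seg_len[is_exon] <- sample(
    seq(config$exon_length[1], config$exon_length[2]),
    sum(is_exon),
    replace = TRUE
  )
  seg_len[!is_exon] <- sample(
    seq(config$intron_length[1], config$intron_length[2]),
    sum(!is_exon),
    replace = TRUE
  )
  gene_len <- vapply(split(seg_len, seg_gene), sum, numeric(1))

  chrom_idx <- (seq_len(n) - 1L) %/% config$genes_per_chrom + 1L
  gap <- sample(
    seq(config$intergenic_gap[1], config$intergenic_gap[2]), n,
    replace = TRUE
  )
  # gene start = cumulative (gap + previous gene lengths) within chromosome
  offset <- unlist(lapply(split(gap + gene_len, chrom_idx), function(v) {
    cumsum(v) - v
  }), use.names = FALSE)
  gene_start <- offset + gap

  seg_start <- gene_start[seg_gene] +
    unlist(lapply(split(seg_len, seg_gene), function(v) cumsum(v) - v),
      use.names = FALSE
    )
  exons <- tibble(
    gene_id = gene_id[seg_gene[is_exon]],
    chrom = paste0("chr", chrom_idx[seg_gene[is_exon]]),
    start = seg_start[is_exon],
    end = seg_start[is_exon] + seg_len[is_exon],
    strand = strand[seg_gene[is_exon]]
  )
  ann <- gene_annotation(exons)

  truth <- tibble(
    gene_id = gene_id,
    class = class,
    p_conventional = unname(config$p_conventional[class]),
    p_antisense = unname(config$p_antisense[class]),
    p_retention = unname(config$p_retention[class]),
    p_premrna = unname(config$p_premrna[class])
  )
  list(ann = ann, truth = truth)
}

#' Simulate a per-cytosine bisulfite methylation table
#'
#' Cytosine sites are placed uniformly within each gene span at the
#' configured per-context densities. Each site is truly methylated with the
#' class- and context-specific rate; read counts are binomial at
#' `meth_read_rate` for methylated and `error_rate` (non-conversion) for
#' unmethylated sites, with Poisson coverage.
#'
#' @param ann A [gene_annotation].
#' @param truth Truth table from [simulate_genes()].
#' @param config A [sim_config()].
#' @return A tibble in cytosine-report layout (chrom, pos 0-based, strand,
#'   context, meth_reads, unmeth_reads).
#' @export
simulate_methylation <- function(ann, truth, config) {
  genes <- ann$genes |> inner_join(truth |> select("gene_id", "class"), by = "gene_id")
  per_ctx <- purrr::map(c(CG = "CG", CHG = "CHG", CHH = "CHH"), function(ctx) {
    n_sites <- pmax(1L, round(genes$length * config$site_density[[ctx]]))
    g <- rep(seq_len(nrow(genes)), n_sites)
    pos <- genes$start[g] + floor(runif(length(g)) * genes$length[g])
    rate_by_class <- vapply(config$site_rates, `[[`, numeric(1), ctx)
    state <- runif(length(g)) < rate_by_class[genes$class[g]]
    tibble(
      chrom = genes$chrom[g],
      pos = as.integer(pos),
      strand = sample(c("+", "-"), length(g), replace = TRUE),
      context = ctx,
      state = state
    )
  })
  sites <- bind_rows(per_ctx)
  cov <- pmax(1L, rpois(nrow(sites), config$coverage_mean))
  p_read <- if_else(sites$state, config$meth_read_rate, config$error_rate)
  meth <- rbinom(nrow(sites), cov, p_read)
  sites |>
    mutate(meth_reads = meth, unmeth_reads = cov - meth) |>
    select("chrom", "pos", "strand", "context", "meth_reads", "unmeth_reads") |>
    arrange(.data$chrom, .data$pos, .data$context)
}

#' Simulate full-length spliced long reads with planted effects
#'
#' Per gene, a negative-binomial number of reads. Each read is antisense with
#' the planted class probability (antisense reads span the whole gene, fully
#' spliced); sense reads start at the annotated exon-1 start with probability
#' `p_conventional`, otherwise at a uniform position 3' of the exon-1 start.
#' With probability `p_retention` a sense read retains one uniformly chosen
#' intron (an internal-start retaining read starts 5' of that intron so the
#' retained intron remains covered); all other introns covered by the read
#' are spliced out.
#'
#' @param ann A [gene_annotation].
#' @param truth Truth table from [simulate_genes()].
#' @param config A [sim_config()].
#' @param gene_rates Optional per-gene override tibble (gene_id plus any of
#'   p_conventional, p_antisense, p_retention) for planting effects as gene
#'   properties rather than class effects.
#' @return A list: `reads` (a spliced-read block tibble, see
#'   [spliced_reads()]) and `read_truth` (per-read planted attributes).
#' @export
simulate_long_reads <- function(ann, truth, config, gene_rates = NULL) {
  params <- truth
  if (!is.null(gene_rates)) {
    keep <- setdiff(names(params), setdiff(names(gene_rates), "gene_id"))
    params <- params |>
      select(dplyr::all_of(keep)) |>
      inner_join(gene_rates, by = "gene_id")
  }
  genes <- ann$genes |>
    inner_join(params, by = "gene_id") |>
    left_join(
      ann$introns |> count(.data$gene_id, name = "n_introns"),
      by = "gene_id"
    ) |>
    mutate(n_introns = tidyr::replace_na(.data$n_introns, 0L))

  n_reads <- rnbinom(
    nrow(genes),
    mu = config$reads_per_gene_mean, size = config$reads_per_gene_size
  )
  g <- rep(seq_len(nrow(genes)), n_reads)
  nr <- length(g)
  rd <- tibble(
    read_id = sprintf("r%07d", seq_len(nr)),
    gene_id = genes$gene_id[g],
    chrom = genes$chrom[g],
    gene_strand = genes$strand[g],
    gene_start = genes$start[g],
    gene_end = genes$end[g],
    gene_len = genes$length[g],
    n_introns = genes$n_introns[g],
    antisense = runif(nr) < genes$p_antisense[g],
    conventional = runif(nr) < genes$p_conventional[g],
    retain = runif(nr) < genes$p_retention[g] & genes$n_introns[g] > 0L,
    retained_rank = if_else(
      genes$n_introns[g] > 0L,
      as.integer(floor(runif(nr) * genes$n_introns[g])) + 1L,
      NA_integer_
    )
  ) |>
    mutate(
      conventional = if_else(.data$antisense, NA, .data$conventional),
      retain = if_else(.data$antisense, FALSE, .data$retain),
      retained_rank = if_else(.data$retain, .data$retained_rank, NA_integer_)
    )

  # oriented 5' offset of each intron's 5' boundary from the gene 5' end
  intron_offsets <- ann$introns |>
    inner_join(
      ann$genes |> select("gene_id", g_start = "start", g_end = "end"),
      by = "gene_id"
    ) |>
    mutate(offset_5p = if_else(
      .data$strand == "+", .data$start - .data$g_start, .data$g_end - .data$end
    )) |>
    select("gene_id", retained_rank = "intron_rank", "offset_5p")

  rd <- rd |>
    left_join(intron_offsets, by = c("gene_id", "retained_rank")) |>
    mutate(
      # internal-start offset d in [1, L-1]; when retaining, d in [0/1, offset]
      d_max = dplyr::case_when(
        is.na(.data$conventional) ~ 0L, # antisense: full span
        .data$conventional ~ 0L,
        .data$retain ~ as.integer(.data$offset_5p),
        TRUE ~ .data$gene_len - 1L
      ),
      d = if_else(
        .data$d_max > 0L,
        as.integer(floor(runif(dplyr::n()) * .data$d_max)) + 1L,
        0L
      ),
      region_start = if_else(.data$gene_strand == "+",
        .data$gene_start + .data$d, .data$gene_start
      ),
      region_end = if_else(.data$gene_strand == "+",
        .data$gene_end, .data$gene_end - .data$d
      ),
      strand = if_else(.data$antisense,
        if_else(.data$gene_strand == "+", "-", "+"), .data$gene_strand
      )
    )

  # splice out introns fully inside the region, except the retained one
  spliced <- rd |>
    select(
      "read_id", "gene_id", "region_start", "region_end", "retained_rank"
    ) |>
    inner_join(
      ann$introns |>
        select("gene_id", "intron_rank", i_start = "start", i_end = "end"),
      by = "gene_id", relationship = "many-to-many"
    ) |>
    filter(
      .data$i_start >= .data$region_start, .data$i_end <= .data$region_end,
      is.na(.data$retained_rank) | .data$intron_rank != .data$retained_rank
    )

  # a read with k spliced introns has k+1 blocks; sorted left edges pair with
  # sorted right edges one-to-one because the introns are disjoint
  left_edges <- bind_rows(
    rd |> select("read_id", edge = "region_start"),
    spliced |> select("read_id", edge = "i_end")
  )
  right_edges <- bind_rows(
    rd |> select("read_id", edge = "region_end"),
    spliced |> select("read_id", edge = "i_start")
  )
  le <- left_edges[order(left_edges$read_id, left_edges$edge), ]
  re <- right_edges[order(right_edges$read_id, right_edges$edge), ]
  stopifnot(identical(le$read_id, re$read_id))
  blocks <- tibble(
    read_id = le$read_id, start = le$edge, end = re$edge
  ) |>
    filter(.data$start < .data$end) |>
    inner_join(rd |> select("read_id", "chrom", "strand"), by = "read_id")

  read_truth <- rd |>
    select(
      "read_id", "gene_id", "antisense", "conventional", "retain",
      "retained_rank", internal_offset = "d"
    )
  list(reads = spliced_reads(blocks), read_truth = read_truth)
}

#' Simulate short-read RNA-seq intervals with planted components
#'
#' Per gene, a Poisson number of single-interval reads drawn from three
#' components: baseline exonic coverage (uniform over exonic bases of the
#' whole gene), an internal-initiation component (uniform over exonic bases
#' 3' of exon 1, with weight proportional to the planted internal-start rate
#' `1 - p_conventional`), and an intron component (uniform over intron bases,
#' weight proportional to the planted retention rate). Reads are clipped to
#' their source feature so each stays a single interval.
#'
#' @inheritParams simulate_long_reads
#' @param depth_mean Mean reads per gene (default from config).
#' @return A list: `reads` (tibble read_id, chrom, start, end, strand) and
#'   `library_size`.
#' @export
simulate_short_reads <- function(ann, truth, config, gene_rates = NULL,
                                 depth_mean = config$short_reads_per_gene_mean) {
  params <- truth
  if (!is.null(gene_rates)) {
    keep <- setdiff(names(params), setdiff(names(gene_rates), "gene_id"))
    params <- params |>
      select(dplyr::all_of(keep)) |>
      inner_join(gene_rates, by = "gene_id")
  }
  genes <- ann$genes |> inner_join(params, by = "gene_id")
  n_reads <- rpois(nrow(genes), depth_mean)
  g <- rep(seq_len(nrow(genes)), n_reads)
  nr <- length(g)
  p_internal <- config$short_internal_weight * (1 - genes$p_conventional[g])
  p_intron <- config$short_intron_weight * genes$p_premrna[g]
  u <- runif(nr)
  category <- dplyr::case_when(
    u < p_intron ~ "intron",
    u < p_intron + p_internal ~ "internal",
    TRUE ~ "base"
  )

  feats <- bind_rows(
    ann$exons |>
      mutate(kind = "exon", downstream = .data$exon_rank >= 2L) |>
      select("gene_id", "chrom", "start", "end", "strand", "kind", "downstream"),
    ann$introns |>
      mutate(kind = "intron", downstream = TRUE) |>
      select("gene_id", "chrom", "start", "end", "strand", "kind", "downstream")
  ) |>
    mutate(width = .data$end - .data$start, fid = row_number())

  # width-proportional feature sampling via per-gene cumulative weights:
  # feats are sorted by gene; a read draws a uniform point in its gene's
  # category-weight mass and findInterval maps it to a feature row
  feats <- feats |> arrange(.data$gene_id, .data$fid)
  gene_of_read <- genes$gene_id[g]
  sel <- integer(nr)
  weight_of <- list(
    base = function(f) if_else(f$kind == "exon", f$width, 0L),
    internal = function(f) if_else(f$kind == "exon" & f$downstream, f$width, 0L),
    intron = function(f) if_else(f$kind == "intron", f$width, 0L)
  )
  gene_totals <- function(w) {
    rowsum(w, feats$gene_id)[, 1]
  }
  for (cat in c("base", "internal", "intron")) {
    idx <- which(category == cat)
    if (length(idx) == 0) next
    w <- weight_of[[cat]](feats)
    tot <- gene_totals(w)
    # a category with no mass in a gene falls back to baseline exon coverage
    none <- idx[tot[gene_of_read[idx]] == 0]
    if (length(none) > 0 && cat != "base") {
      category[none] <- "base"
      idx <- setdiff(idx, none)
      if (length(idx) == 0) next
    }
    cum <- cumsum(w)
    offset <- cum - w # mass before each feature row
    gene_first <- !duplicated(feats$gene_id)
    gene_offset <- setNames(offset[gene_first], feats$gene_id[gene_first])
    target <- gene_offset[gene_of_read[idx]] +
      runif(length(idx)) * tot[gene_of_read[idx]]
    sel[idx] <- findInterval(target, cum) + 1L
  }
  idx_base <- which(category == "base" & sel == 0L)
  if (length(idx_base) > 0) { # fallback reads routed to base above
    w <- weight_of$base(feats)
    tot <- gene_totals(w)
    cum <- cumsum(w)
    offset <- cum - w
    gene_first <- !duplicated(feats$gene_id)
    gene_offset <- setNames(offset[gene_first], feats$gene_id[gene_first])
    target <- gene_offset[gene_of_read[idx_base]] +
      runif(length(idx_base)) * tot[gene_of_read[idx_base]]
    sel[idx_base] <- findInterval(target, cum) + 1L
  }

  chosen <- feats[sel, ]
  pos <- chosen$start + floor(runif(nr) * chosen$width)
  reads <- tibble(
    read_id = sprintf("s%07d", seq_len(nr)),
    chrom = chosen$chrom,
    start = as.integer(pos),
    end = as.integer(pmin(pos + config$short_read_length, chosen$end)),
    strand = chosen$strand
  )
  list(reads = reads, library_size = nrow(reads))
}

#' Write a complete synthetic input bundle
#'
#' Simulates annotation, methylation, long reads and short reads under one
#' seed and writes the file bundle every pipeline stage consumes: `genes.gff3`,
#' `cytosine_report.tsv` (Bismark-style), `long_reads.bed` (BED12),
#' `short_reads.bed` (BED6), `truth.tsv` and `meta.json`. Identical
#' (config, seed) pairs produce byte-identical bundles.
#'
#' @param config A [sim_config()].
#' @param seed Integer RNG seed.
#' @param dir Output directory (created if needed).
#' @param gene_rates Optional per-gene parameter overrides, see
#'   [simulate_long_reads()].
#' @return Invisibly, a list with `paths` (named file paths) and the
#'   in-memory objects (`ann`, `truth`, `reads`, `read_truth`, `short_reads`,
#'   `library_size`).
#' @export
simulate_dataset <- function(config, seed, dir, gene_rates = NULL) {
  validate_sim_config(config)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(seed)

  sim <- simulate_genes(config)
  meth <- simulate_methylation(sim$ann, sim$truth, config)
  lr <- simulate_long_reads(sim$ann, sim$truth, config, gene_rates = gene_rates)
  sr <- simulate_short_reads(sim$ann, sim$truth, config, gene_rates = gene_rates)

  paths <- list(
    gff3 = file.path(dir, "genes.gff3"),
    cytosine_report = file.path(dir, "cytosine_report.tsv"),
    long_reads = file.path(dir, "long_reads.bed"),
    short_reads = file.path(dir, "short_reads.bed"),
    truth = file.path(dir, "truth.tsv"),
    meta = file.path(dir, "meta.json")
  )

  write_gene_annotation(sim$ann, paths$gff3)

  tri <- c(CG = "CGA", CHG = "CAG", CHH = "CAT")
  readr::write_tsv(
    meth |>
      mutate(pos = .data$pos + 1L, tri = tri[.data$context]) |>
      select(
        "chrom", "pos", "strand", "meth_reads", "unmeth_reads", "context", "tri"
      ),
    paths$cytosine_report,
    col_names = FALSE
  )

  write_bed12(lr$reads, paths$long_reads)

  sr_gr <- as_granges0(sr$reads)
  S4Vectors::mcols(sr_gr)$name <- sr$reads$read_id
  rtracklayer::export(sr_gr, paths$short_reads, format = "bed")

  realized <- lr$read_truth |> count(.data$gene_id, name = "n_long_reads")
  truth_out <- sim$truth |>
    left_join(realized, by = "gene_id") |>
    mutate(n_long_reads = tidyr::replace_na(.data$n_long_reads, 0L))
  readr::write_tsv(truth_out, paths$truth)

  jsonlite::write_json(
    list(
      n_genes = config$n_genes, seed = seed,
      library_size = sr$library_size,
      n_long_reads = nrow(lr$read_truth |> distinct(.data$read_id))
    ),
    paths$meta,
    auto_unbox = TRUE
  )

  invisible(list(
    paths = paths,
    ann = sim$ann, truth = truth_out, reads = lr$reads,
    read_truth = lr$read_truth, short_reads = sr$reads,
    library_size = sr$library_size
  ))
}

# BED12 writer via rtracklayer: blocks are feature-relative
write_bed12 <- function(blocks, path) {
  per_read <- blocks |>
    group_by(.data$read_id) |>
    summarise(
      chrom = first(.data$chrom),
      strand = first(.data$strand),
      f_start = min(.data$start),
      f_end = max(.data$end),
      .groups = "drop"
    )
  gr <- GenomicRanges::GRanges(
    per_read$chrom,
    IRanges::IRanges(per_read$f_start + 1L, per_read$f_end),
    strand = per_read$strand
  )
  S4Vectors::mcols(gr)$name <- per_read$read_id
  rel <- blocks |>
    inner_join(per_read |> select("read_id", "f_start"), by = "read_id") |>
    arrange(match(.data$read_id, per_read$read_id), .data$start)
  S4Vectors::mcols(gr)$blocks <- S4Vectors::split(
    IRanges::IRanges(rel$start - rel$f_start + 1L, rel$end - rel$f_start),
    factor(rel$read_id, levels = per_read$read_id)
  )
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Load the planted truth table of a simulated bundle
#'
#' @param dir Bundle directory written by [simulate_dataset()].
#' @return The truth tibble (gene_id, class, planted parameters, realized
#'   long-read counts). Errors when the truth file is missing or the bundle
#'   is inconsistent with its annotation.
#' @export
planted_truth <- function(dir) {
  tf <- file.path(dir, "truth.tsv")
  gf <- file.path(dir, "genes.gff3")
  if (!file.exists(tf)) abort("truth.tsv missing from bundle")
  if (!file.exists(gf)) abort("genes.gff3 missing from bundle")
  truth <- readr::read_tsv(tf, show_col_types = FALSE, progress = FALSE)
  ann <- read_gene_annotation(gf)
  if (!setequal(truth$gene_id, ann$genes$gene_id)) {
    abort("bundle inconsistent: truth table and annotation name different genes")
  }
  truth
}
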