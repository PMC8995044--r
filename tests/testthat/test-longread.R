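bed12_file <- function(lines) {
  f <- withr::local_tempfile(fileext = ".bed", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("BED12 blocks parse to genomic half-open intervals with 5' starts", {
  f <- bed12_file(c(
    "chr1\t0\t400\trA\t0\t+\t0\t400\t0\t2\t100,100\t0,300",
    "chr1\t0\t400\trB\t0\t-\t0\t400\t0\t2\t100,100\t0,300"
  ))
  reads <- read_spliced_reads(f)
  ra <- reads[reads$read_id == "rA", ]
  expect_equal(ra$start, c(0, 300))
  expect_equal(ra$end, c(100, 400))
  expect_equal(unique(ra$read_start_5p), 0)
  rb <- reads[reads$read_id == "rB", ]
  expect_equal(unique(rb$read_start_5p), 399)

  bad <- bed12_file("chr1\t0\t400\trC\t0\t+\t0\t400\t0\t2\t100\t0,300")
  expect_error(read_spliced_reads(bad), "BED12|malformed|block")
})

test_that("reads assign to the gene with maximal overlap above the 50% rule", {
  ann <- gene_annotation(tibble::tibble(
    gene_id = c("gA", "gB"), chrom = "chr1",
    start = c(0, 1000), end = c(900, 1100), strand = "+"
  ))
  reads <- spliced_reads(tibble::tibble(
    read_id = c("inside", "split", "split", "mostly_out"),
    chrom = "chr1", strand = "+",
    start = c(100, 800, 1000, 850),
    end = c(500, 900, 1100, 1100) # split: 100bp in gA, 100bp in gB -> tie
  ))
  asg <- assign_reads_to_genes(reads, ann)
  expect_equal(asg$gene_id[asg$read_id == "inside"], "gA")
  expect_true(is.na(asg$gene_id[asg$read_id == "split"])) # exact tie
  # mostly_out: 50bp in gA, 100bp in gB of 250 aligned bp -> 40% < 50%
  expect_true(is.na(asg$gene_id[asg$read_id == "mostly_out"]))

  big <- spliced_reads(tibble::tibble(
    read_id = "dominant", chrom = "chr1", strand = "+",
    start = c(100, 1000), end = c(900, 1100)
  ))
  expect_equal(
    assign_reads_to_genes(big, ann)$gene_id, "gA" # 800 vs 100 bp
  )
})

test_that("TSS, antisense and retention calls follow the definitions", {
  # + strand gene: exons (0,100),(200,300),(400,500); introns (100,200),(300,400)
  ann <- gene_annotation(tibble::tibble(
    gene_id = "g", chrom = "chr1",
    start = c(0, 200, 400), end = c(100, 300, 500), strand = "+"
  ))
  reads <- spliced_reads(tibble::tibble(
    read_id = c(
      "conv_spliced", "conv_spliced", "conv_spliced",
      "start_in_intron1",
      "retains_intron1", "retains_intron1",
      "antisense",
      "one_bp_in"
    ),
    chrom = "chr1",
    strand = c(rep("+", 6), "-", "+"),
    start = c(0, 200, 400, 150, 0, 400, 0, 1),
    end = c(100, 300, 500, 500, 300, 500, 500, 500)
  ))
  calls <- classify_reads(reads, ann)

  conv <- calls[calls$read_id == "conv_spliced", ]
  expect_false(conv$antisense)
  expect_true(conv$tss_conventional)
  expect_equal(conv$retained_introns[[1]], integer())

  sii <- calls[calls$read_id == "start_in_intron1", ]
  expect_false(sii$tss_conventional)
  expect_true(sii$tss_in_intron)

  ret <- calls[calls$read_id == "retains_intron1", ]
  expect_true(ret$tss_conventional) # starts at exon-1 start
  expect_equal(ret$retained_introns[[1]], 1L) # block (0,300) contains intron 1

  anti <- calls[calls$read_id == "antisense", ]
  expect_true(anti$antisense)
  expect_true(is.na(anti$tss_conventional))

  # started 1 bp after exon-1 start -> nonconventional at tolerance 0
  expect_false(calls$tss_conventional[calls$read_id == "one_bp_in"])
  calls_tol <- classify_reads(reads, ann, tss_tolerance = 1)
  expect_true(calls_tol$tss_conventional[calls_tol$read_id == "one_bp_in"])
})

test_that("classification matches the per-base brute-force oracle on random cases", {
  set.seed(101)
  n_agree <- 0
  for (i in 1:120) {
    gene <- random_gene()
    read_blocks <- random_read_for_gene(gene)
    reads <- spliced_reads(read_blocks)
    calls <- classify_reads(reads, gene)
    expect_equal(nrow(calls), 1)
    oracle <- oracle_classify_read(
      read_blocks |> dplyr::select(start, end),
      read_blocks$strand[1], gene
    )
    expect_identical(calls$antisense, oracle$antisense)
    expect_identical(calls$tss_conventional, oracle$tss_conventional)
    if (!calls$antisense) {
      expect_identical(calls$tss_in_intron, oracle$tss_in_intron)
    }
    expect_identical(
      as.integer(calls$retained_introns[[1]]),
      as.integer(oracle$retained_introns)
    )
    n_agree <- n_agree + 1
  }
  expect_equal(n_agree, 120)
})

test_that("per-gene metrics: arithmetic, denominators, undefined cases", {
  ann <- gene_annotation(tibble::tibble(
    gene_id = c(rep("gM", 2), "gSingle"), chrom = "chr1",
    start = c(0, 200, 1000), end = c(100, 300, 1200),
    strand = "+"
  ))
  # gM: 10 sense reads (8 conventional, 2 of them retaining), 1 antisense
  mk_calls <- function() {
    tibble::tibble(
      read_id = sprintf("r%02d", 1:11),
      gene_id = "gM",
      strand = "+",
      antisense = c(rep(FALSE, 10), TRUE),
      tss_conventional = c(rep(TRUE, 8), FALSE, FALSE, NA),
      tss_in_intron = FALSE,
      n_retained = c(1L, 1L, rep(0L, 9)),
      retained_introns = c(list(1L), list(1L), rep(list(integer()), 9))
    )
  }
  m <- gene_longread_metrics(mk_calls(), ann)
  expect_equal(m$prop_conventional_tss, 0.8)
  expect_equal(m$prop_antisense, 1 / 11)
  expect_equal(m$prop_intron_retained, 0.2)
  expect_equal(m$expression_proxy, 11)
  # conventional + nonconventional == sense; sense + antisense == assigned
  expect_equal(m$n_conventional + sum(!is.na(mk_calls()$tss_conventional) &
    !mk_calls()$tss_conventional), m$n_sense)
  expect_equal(m$n_sense + m$n_antisense, m$n_reads)

  # below min_reads -> proportions undefined
  few <- mk_calls()[1:3, ]
  m_few <- gene_longread_metrics(few, ann, min_reads = 5)
  expect_true(is.na(m_few$prop_conventional_tss))

  # single-exon gene: retention undefined, others computed
  single_calls <- tibble::tibble(
    read_id = sprintf("s%d", 1:6), gene_id = "gSingle", strand = "+",
    antisense = FALSE, tss_conventional = TRUE, tss_in_intron = FALSE,
    n_retained = 0L, retained_introns = list(integer())
  )
  ms <- gene_longread_metrics(single_calls, ann)
  expect_true(is.na(ms$prop_intron_retained))
  expect_equal(ms$prop_conventional_tss, 1)
})

test_that("metrics are invariant under genome reflection (strand symmetry)", {
  set.seed(103)
  cfg <- sim_config(
    n_genes = 40L, genes_per_chrom = 20L, reads_per_gene_mean = 8
  )
  sim <- simulate_genes(cfg)
  lr <- simulate_long_reads(sim$ann, sim$truth, cfg)
  m1 <- gene_longread_metrics(classify_reads(lr$reads, sim$ann), sim$ann,
    min_reads = 1
  )

  pivot <- max(sim$ann$genes$end) + 1000L
  flip <- function(df) {
    df |> dplyr::mutate(
      s2 = pivot - end, e2 = pivot - start,
      strand = ifelse(strand == "+", "-", "+")
    ) |>
      dplyr::select(-start, -end) |>
      dplyr::rename(start = s2, end = e2)
  }
  ann2 <- gene_annotation(
    flip(sim$ann$exons) |> dplyr::select(gene_id, chrom, start, end, strand)
  )
  reads2 <- spliced_reads(
    flip(lr$reads) |> dplyr::select(read_id, chrom, strand, start, end)
  )
  m2 <- gene_longread_metrics(classify_reads(reads2, ann2), ann2, min_reads = 1)

  key <- c(
    "gene_id", "n_reads", "n_sense", "n_antisense", "n_conventional",
    "prop_conventional_tss", "prop_antisense", "prop_intron_retained"
  )
  expect_equal(
    m1 |> dplyr::select(dplyr::all_of(key)) |> dplyr::arrange(gene_id),
    m2 |> dplyr::select(dplyr::all_of(key)) |> dplyr::arrange(gene_id)
  )
})
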