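gff3_text <- function(...) {
  lines <- c("##gff-version 3", ...)
  f <- withr::local_tempfile(fileext = ".gff3", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("GFF3 coordinates convert to 0-based half-open and introns are gaps", {
  f <- gff3_text(
    "chr1\tsrc\tgene\t101\t400\t.\t+\t.\tID=gA",
    "chr1\tsrc\tmRNA\t101\t400\t.\t+\t.\tID=gA.1;Parent=gA",
    "chr1\tsrc\texon\t101\t200\t.\t+\t.\tParent=gA.1",
    "chr1\tsrc\texon\t301\t400\t.\t+\t.\tParent=gA.1"
  )
  ann <- read_gene_annotation(f)
  expect_equal(ann$exons$start, c(100, 300))
  expect_equal(ann$exons$end, c(200, 400))
  expect_equal(ann$introns$start, 200)
  expect_equal(ann$introns$end, 300)
  expect_equal(ann$genes$length, 300)
})

test_that("on the minus strand exon 1 is the rightmost exon", {
  ex <- tibble::tibble(
    gene_id = "gB", chrom = "chr1",
    start = c(100, 300), end = c(200, 400), strand = "-"
  )
  ann <- gene_annotation(ex)
  e1 <- ann$exons[ann$exons$exon_rank == 1, ]
  expect_equal(e1$start, 300)
  expect_equal(e1$end, 400)
  expect_equal(ann$introns$intron_rank, 1L)
  expect_equal(c(ann$introns$start, ann$introns$end), c(200, 300))
})

test_that("derive_introns handles boundaries and rejects overlap", {
  ex3 <- tibble::tibble(
    gene_id = "g", exon_rank = 1:3, chrom = "c",
    start = c(0, 200, 400), end = c(100, 300, 500), strand = "+"
  )
  introns <- derive_introns(ex3)
  expect_equal(introns$start, c(100, 300))
  expect_equal(introns$end, c(200, 400))

  single <- ex3[1, ]
  expect_equal(nrow(derive_introns(single)), 0)

  minus <- tibble::tibble(
    gene_id = "g", exon_rank = 1:2, chrom = "c",
    start = c(400, 0), end = c(500, 100), strand = "-"
  )
  expect_equal(derive_introns(minus)$start, 100)
  expect_equal(derive_introns(minus)$end, 400)

  overlapping <- tibble::tibble(
    gene_id = "g", exon_rank = 1:2, chrom = "c",
    start = c(0, 50), end = c(100, 150), strand = "+"
  )
  expect_error(derive_introns(overlapping), "overlap")
})

test_that("canonical transcript is longest summed exons, ties to smallest id", {
  tx <- tibble::tibble(
    transcript_id = c("t2", "t2", "t1"),
    start = c(0, 700, 0), end = c(600, 1300, 900)
  )
  expect_equal(unique(select_canonical(tx)$transcript_id), "t2") # 1200 > 900

  tie <- tibble::tibble(
    transcript_id = c("AT1G01010.2", "AT1G01010.1"),
    start = c(0, 100), end = c(500, 600)
  )
  expect_equal(unique(select_canonical(tie)$transcript_id), "AT1G01010.1")

  one <- tibble::tibble(transcript_id = "t9", start = 0, end = 10)
  expect_equal(select_canonical(one), one)
  expect_error(select_canonical(one[0, ]), "no transcripts")
})

test_that("multi-isoform GFF3 picks the canonical transcript per gene", {
  f <- gff3_text(
    "chr1\tsrc\tgene\t1\t1000\t.\t+\t.\tID=gC",
    "chr1\tsrc\tmRNA\t1\t1000\t.\t+\t.\tID=gC.1;Parent=gC",
    "chr1\tsrc\texon\t1\t100\t.\t+\t.\tParent=gC.1",
    "chr1\tsrc\texon\t901\t1000\t.\t+\t.\tParent=gC.1",
    "chr1\tsrc\tmRNA\t1\t1000\t.\t+\t.\tID=gC.2;Parent=gC",
    "chr1\tsrc\texon\t1\t500\t.\t+\t.\tParent=gC.2",
    "chr1\tsrc\texon\t901\t1000\t.\t+\t.\tParent=gC.2"
  )
  ann <- read_gene_annotation(f)
  expect_equal(sum(ann$exons$end - ann$exons$start), 600) # gC.2 wins
  ann_union <- read_gene_annotation(f, isoform = "union")
  expect_equal(sum(ann_union$exons$end - ann_union$exons$start), 600)
})

test_that("a gene whose mRNA has no exons is skipped with a warning", {
  f <- gff3_text(
    "chr1\tsrc\tgene\t1\t100\t.\t+\t.\tID=gD",
    "chr1\tsrc\tmRNA\t1\t100\t.\t+\t.\tID=gD.1;Parent=gD",
    "chr1\tsrc\tgene\t201\t400\t.\t+\t.\tID=gE",
    "chr1\tsrc\tmRNA\t201\t400\t.\t+\t.\tID=gE.1;Parent=gE",
    "chr1\tsrc\texon\t201\t400\t.\t+\t.\tParent=gE.1"
  )
  expect_warning(ann <- read_gene_annotation(f), "skipped")
  expect_equal(ann$genes$gene_id, "gE")
})

test_that("GFF3 round trip reproduces the gene models exactly", {
  set.seed(41)
  exs <- dplyr::bind_rows(lapply(1:8, function(i) {
    g <- random_gene(n_exons = sample(1:5, 1))
    g$exons |>
      dplyr::mutate(gene_id = sprintf("g%02d", i), start = start + 1000L * i,
                    end = end + 1000L * i)
  }))
  ann <- gene_annotation(exs |> dplyr::select(gene_id, chrom, start, end, strand))
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gene_annotation(ann, f)
  ann2 <- read_gene_annotation(f)
  expect_equal(ann2$genes, ann$genes)
  expect_equal(ann2$exons, ann$exons)
  expect_equal(ann2$introns, ann$introns)
})

test_that("exon plus intron lengths equal the span length for every gene", {
  set.seed(42)
  for (i in 1:20) {
    ann <- random_gene()
    exonic <- sum(ann$exons$end - ann$exons$start)
    intronic <- sum(ann$introns$end - ann$introns$start)
    expect_equal(exonic + intronic, ann$genes$length)
  }
})

test_that("reflecting coordinates and flipping strand mirrors the model", {
  set.seed(43)
  for (i in 1:10) {
    ann <- random_gene()
    pivot <- 10000L
    flipped <- ann$exons |>
      dplyr::mutate(
        s2 = pivot - end, e2 = pivot - start,
        strand = ifelse(strand == "+", "-", "+")
      ) |>
      dplyr::select(gene_id, chrom, start = s2, end = e2, strand)
    ann2 <- gene_annotation(flipped)
    expect_equal(ann2$genes$n_exons, ann$genes$n_exons)
    expect_equal(ann2$genes$length, ann$genes$length)
    # exon k of the mirror has the same length as exon k of the original
    expect_equal(
      ann2$exons$end - ann2$exons$start,
      ann$exons$end - ann$exons$start
    )
    expect_equal(
      ann2$introns$end - ann2$introns$start,
      ann$introns$end - ann$introns$start
    )
  }
})

test_that("malformed GFF3 raises a parse error", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "chr1\tonly\tthree"), f)
  expect_error(read_gene_annotation(f), "GFF3")
})
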