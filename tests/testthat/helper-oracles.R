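# Independent oracles used across the suite. These deliberately use the
# slowest, most literal formulation of each definition (per-base set
# membership, exhaustive enumeration, direct density sums) so they share no
# code path with the package implementation.

# exact binomial tails by direct density summation
oracle_binom_upper <- function(k, n, p) sum(dbinom(k:n, n, p))
oracle_binom_lower <- function(k, n, p) sum(dbinom(0:k, n, p))

# exhaustive Mann-Whitney enumeration over all C(n+m, n) group labelings.
# Returns the p-value for the observed U of group a.
oracle_wilcoxon <- function(a, b, alternative = "two_sided") {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled)) # tie-free inputs only
  n <- length(a)
  u_of <- function(x, y) sum(outer(x, y, ">"))
  u_obs <- u_of(a, b)
  combs <- utils::combn(length(pooled), n)
  u_all <- apply(combs, 2, function(i) u_of(pooled[i], pooled[-i]))
  switch(alternative,
    a_less = mean(u_all <= u_obs),
    a_greater = mean(u_all >= u_obs),
    two_sided = min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
  )
}

# per-base read classification: explicit base-set membership for TSS and
# intron containment, one read against one gene model
oracle_classify_read <- function(read_blocks, read_strand, gene) {
  g <- gene$genes
  stopifnot(nrow(g) == 1)
  antisense <- read_strand != g$strand
  base_sets <- lapply(seq_len(nrow(read_blocks)), function(i) {
    seq(read_blocks$start[i], read_blocks$end[i] - 1L)
  })
  all_bases <- sort(unlist(base_sets))
  start_5p <- if (read_strand == "+") min(all_bases) else max(all_bases)

  e1 <- gene$exons[gene$exons$exon_rank == 1L, ]
  e1_start_oriented <- if (g$strand == "+") e1$start else e1$end - 1L
  tss_conventional <- if (antisense) {
    NA
  } else if (g$strand == "+") {
    start_5p <= e1_start_oriented
  } else {
    start_5p >= e1_start_oriented
  }

  tss_in_intron <- FALSE
  if (!antisense && isFALSE(tss_conventional) && nrow(gene$introns) > 0) {
    for (i in seq_len(nrow(gene$introns))) {
      ib <- seq(gene$introns$start[i], gene$introns$end[i] - 1L)
      if (start_5p %in% ib) tss_in_intron <- TRUE
    }
  }

  retained <- integer()
  if (nrow(gene$introns) > 0) {
    for (i in seq_len(nrow(gene$introns))) {
      intron_bases <- seq(gene$introns$start[i], gene$introns$end[i] - 1L)
      contained_in_one_block <- any(vapply(
        base_sets, function(bs) all(intron_bases %in% bs), logical(1)
      ))
      if (contained_in_one_block) retained <- c(retained, gene$introns$intron_rank[i])
    }
  }
  list(
    antisense = antisense,
    tss_conventional = tss_conventional,
    tss_in_intron = tss_in_intron,
    retained_introns = sort(retained)
  )
}

# per-base overlap counting oracle (>= 1 shared base)
oracle_count_overlaps <- function(reads, feature) {
  f_bases <- seq(feature$start, feature$end - 1L)
  sum(vapply(seq_len(nrow(reads)), function(i) {
    r_bases <- seq(reads$start[i], reads$end[i] - 1L)
    any(r_bases %in% f_bases)
  }, logical(1)))
}

# random single-gene model for property tests
random_gene <- function(n_exons = sample(1:5, 1), strand = sample(c("+", "-"), 1),
                        chrom = "chrT") {
  exon_len <- sample(20:60, n_exons, replace = TRUE)
  intron_len <- if (n_exons > 1) sample(15:40, n_exons - 1, replace = TRUE) else integer()
  seg <- integer(0)
  for (i in seq_len(n_exons)) {
    seg <- c(seg, exon_len[i])
    if (i < n_exons) seg <- c(seg, intron_len[i])
  }
  offset <- sample(0:100, 1)
  starts <- offset + cumsum(c(0L, seg[-length(seg)]))
  ends <- offset + cumsum(seg)
  is_exon <- seq_along(seg) %% 2L == 1L
  gene_annotation(tibble::tibble(
    gene_id = "g1", chrom = chrom,
    start = starts[is_exon], end = ends[is_exon], strand = strand
  ))
}

# random spliced read within a gene: start offset within the span, randomly
# spliced/retained introns, possibly antisense
random_read_for_gene <- function(gene, read_id = "r1") {
  g <- gene$genes
  antisense <- runif(1) < 0.3
  read_strand <- if (antisense) setdiff(c("+", "-"), g$strand) else g$strand
  d <- sample(0:(g$length - 2L), 1)
  rs <- if (g$strand == "+") g$start + d else g$start
  re <- if (g$strand == "+") g$end else g$end - d
  introns <- gene$introns[gene$introns$start >= rs & gene$introns$end <= re, ]
  if (nrow(introns) > 0) {
    spliced <- introns[runif(nrow(introns)) < 0.6, ]
  } else {
    spliced <- introns
  }
  edges_l <- sort(c(rs, spliced$end))
  edges_r <- sort(c(spliced$start, re))
  keep <- edges_l < edges_r
  tibble::tibble(
    read_id = read_id, chrom = g$chrom, strand = read_strand,
    start = edges_l[keep], end = edges_r[keep]
  )
}
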