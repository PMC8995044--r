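report_file <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("cytosine report parsing: coordinates, coverage filter, bad context", {
  f <- report_file(c(
    "Chr1\t100\t+\t5\t0\tCG\tCGA",
    "Chr1\t200\t-\t1\t1\tCHG\tCAG", # coverage 2 -> dropped at default 3
    "Chr1\t300\t+\t0\t10\tCHH\tCAT"
  ))
  sites <- read_cytosine_report(f)
  expect_equal(sites$pos, c(99, 299))
  expect_equal(sites$context, c("CG", "CHH"))
  expect_equal(sites$meth_reads, c(5, 0))

  sites_all <- read_cytosine_report(f, min_coverage = 2)
  expect_equal(nrow(sites_all), 3)

  f_bad <- report_file("Chr1\t100\t+\t5\t0\tCNN\tCNN")
  expect_error(read_cytosine_report(f_bad), "context")
  f_nonint <- report_file("Chr1\t100\t+\tfive\t0\tCG\tCGA")
  expect_error(read_cytosine_report(f_nonint), "non-integer")
})

test_that("site-level calls match the exact binomial oracle", {
  # single high site: p = 0.005^5, methylated at any reasonable threshold
  one <- tibble::tibble(
    chrom = "c", pos = 1L, strand = "+", context = "CG",
    meth_reads = 5L, unmeth_reads = 0L
  )
  called <- call_site_methylation(one, error_rate = 0.005)
  expect_equal(called$p_site, 0.005^5)
  expect_true(called$methylated)

  # all-unmethylated site: upper tail p = 1
  zero <- one |> dplyr::mutate(meth_reads = 0L, unmeth_reads = 10L)
  expect_equal(call_site_methylation(zero)$p_site, 1)
  expect_false(call_site_methylation(zero)$methylated)

  # 1/10 at error 0.005: p = 1 - 0.995^10, oracle-checked
  mid <- one |> dplyr::mutate(meth_reads = 1L, unmeth_reads = 9L)
  expect_equal(
    call_site_methylation(mid)$p_site,
    oracle_binom_upper(1, 10, 0.005)
  )
  expect_equal(call_site_methylation(mid)$p_site, 1 - 0.995^10)

  expect_error(
    call_site_methylation(one |> dplyr::mutate(meth_reads = 0L, unmeth_reads = 0L)),
    "zero total"
  )
  expect_error(call_site_methylation(one, error_rate = 0), "error_rate")
})

test_that("site p-values match the dbinom-sum oracle on random (n, k, p) triples", {
  set.seed(7)
  n <- sample(1:60, 300, replace = TRUE)
  k <- vapply(n, function(ni) sample(0:ni, 1), integer(1))
  sites <- tibble::tibble(
    chrom = "c", pos = seq_along(n), strand = "+", context = "CG",
    meth_reads = k, unmeth_reads = n - k
  )
  for (err in c(0.005, 0.05, 0.3)) {
    called <- call_site_methylation(sites, error_rate = err)
    expected <- mapply(function(ki, ni) oracle_binom_upper(ki, ni, err), k, n)
    expect_equal(called$p_site, expected)
  }
})

test_that("background is the pooled methylated-site fraction per context", {
  profiles <- tibble::tibble(
    gene_id = rep(c("g1", "g2"), each = 3),
    context = rep(c("CG", "CHG", "CHH"), 2),
    n_sites = c(100, 50, 10, 100, 50, 10),
    n_meth = c(10, 0, 0, 30, 5, 1)
  )
  bg <- compute_background(profiles)
  expect_equal(bg$p_bg[bg$context == "CG"], 40 / 200)
  expect_equal(bg$p_bg[bg$context == "CHG"], 5 / 100)

  empty_chh <- profiles |> dplyr::mutate(n_sites = ifelse(context == "CHH", 0, n_sites))
  expect_error(compute_background(empty_chh), "CHH")

  # single gene: background equals that gene's own fractions
  single <- profiles[1:3, ]
  expect_equal(compute_background(single)$p_bg, c(0.1, 0, 0))
})

test_that("gene classification recovers gbM / UM / teM on the worked examples", {
  # backgrounds chosen so the examples sit deep in their tails; a panel of
  # identical genes keeps BH adjustment from rescuing borderline cases
  mk_profiles <- function(cg, chg, chh) {
    tidyr::expand_grid(gene_id = sprintf("g%02d", 1:30), tmp = 1) |>
      dplyr::reframe(
        context = c("CG", "CHG", "CHH"),
        n_sites = c(100L, 50L, 80L),
        n_meth = c(cg, chg, chh),
        .by = gene_id
      )
  }
  bg <- tibble::tibble(context = c("CG", "CHG", "CHH"), p_bg = c(0.05, 0.03, 0.02))

  gbm <- classify_genes(mk_profiles(30L, 0L, 0L), bg)
  expect_true(all(gbm$class_label == "gbM"))
  # CG upper-tail p agrees with the oracle (~1.4e-14)
  expect_equal(
    oracle_binom_upper(30, 100, 0.05),
    pbinom(29, 100, 0.05, lower.tail = FALSE)
  )
  expect_lt(oracle_binom_upper(30, 100, 0.05), 1e-13)

  um <- classify_genes(mk_profiles(0L, 0L, 0L), bg)
  expect_true(all(um$class_label == "UM"))
  expect_equal(oracle_binom_lower(0, 100, 0.05), 0.95^100)

  tem <- classify_genes(mk_profiles(40L, 25L, 30L), bg)
  expect_true(all(tem$class_label == "teM")) # CHG upper tail trumps CG

  # too few CG sites -> undetermined with reason, not an error
  sparse <- mk_profiles(5L, 0L, 0L) |>
    dplyr::mutate(n_sites = ifelse(context == "CG", 10L, n_sites))
  out <- classify_genes(sparse, bg)
  expect_true(all(out$class_label == "undetermined"))
  expect_true(all(out$reason == "too_few_cg_sites"))
})

test_that("every gene gets exactly one label and gbM is monotone in CG count", {
  bg <- tibble::tibble(context = c("CG", "CHG", "CHH"), p_bg = c(0.2, 0.05, 0.03))
  set.seed(11)
  profiles <- tidyr::expand_grid(gene_id = sprintf("g%03d", 1:200)) |>
    dplyr::reframe(
      context = c("CG", "CHG", "CHH"),
      n_sites = c(60L, 40L, 50L),
      n_meth = c(
        rbinom(1, 60, sample(c(0.01, 0.2, 0.7), 1)),
        rbinom(1, 40, 0.05), rbinom(1, 40, 0.03)
      ),
      .by = gene_id
    )
  out <- classify_genes(profiles, bg)
  expect_equal(nrow(out), 200)
  expect_true(all(out$class_label %in% c("gbM", "UM", "teM", "undetermined")))

  # sweep one gene's CG count upward; label path must never go gbM -> UM
  labels <- vapply(seq(0, 60, by = 4), function(k) {
    p2 <- profiles |>
      dplyr::mutate(n_meth = ifelse(
        gene_id == "g001" & context == "CG", k, n_meth
      ))
    cls <- classify_genes(p2, bg)
    cls$class_label[cls$gene_id == "g001"]
  }, character(1))
  seen_gbm <- FALSE
  for (lab in labels) {
    if (lab == "gbM") seen_gbm <- TRUE
    if (seen_gbm) expect_true(lab != "UM")
  }
})

test_that("strict mode additionally requires non-CG lower-tail significance", {
  # large gene: CG clearly above background; CHG/CHH at ~background level so
  # their lower tails are not significant
  profiles <- tidyr::expand_grid(gene_id = sprintf("g%02d", 1:20)) |>
    dplyr::reframe(
      context = c("CG", "CHG", "CHH"),
      n_sites = c(100L, 20L, 20L),
      n_meth = c(60L, 2L, 1L),
      .by = gene_id
    )
  bg <- tibble::tibble(context = c("CG", "CHG", "CHH"), p_bg = c(0.2, 0.1, 0.05))
  lax <- classify_genes(profiles, bg, strict = FALSE)
  strict <- classify_genes(profiles, bg, strict = TRUE)
  expect_true(all(lax$class_label == "gbM"))
  expect_true(all(strict$class_label == "undetermined"))
})
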