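test_that("iupac_expand enumerates degenerate sets correctly", {
  m <- iupac_expand("MCGCGB")
  expect_length(m$expansion, 6)
  expect_true("ACGCGT" %in% m$expansion)
  expect_true("CCGCGC" %in% m$expansion)
  expect_false("GCGCGT" %in% m$expansion)

  m2 <- iupac_expand("MCGTGT")
  expect_true("CCGTGT" %in% m2$expansion)
  expect_length(m2$expansion, 2)

  plain <- iupac_expand("ACGT")
  expect_equal(plain$expansion, "ACGT")
  expect_error(iupac_expand("ACGTZ"), "non-IUPAC")
})

test_that("scan_promoter: hand-checked positions, strands, dedup, N", {
  fwd <- scan_promoter("AACGCGTT", "MCGCGB", both_strands = FALSE)
  expect_equal(fwd$count, 1L)
  expect_equal(fwd$positions$start, 2L)

  expect_equal(scan_promoter("", "MCGCGB")$count, 0L)
  expect_equal(scan_promoter("ANGCGT", "MCGCGB")$count, 0L)

  # ACGCGT is its own reverse complement: both-strand scan must not double count
  both <- scan_promoter("AACGCGTT", "MCGCGB", both_strands = TRUE)
  expect_equal(both$count, 1L)

  # a minus-strand-only instance is found only with both_strands
  seq <- paste0("TTTT", oracle_rc("CCGTGT"), "TTTT")
  expect_equal(scan_promoter(seq, "MCGTGT", both_strands = FALSE)$count, 0L)
  expect_equal(scan_promoter(seq, "MCGTGT", both_strands = TRUE)$count, 1L)
})

test_that("scan_promoter equals the sliding-window oracle on random sequence", {
  withr::with_seed(6, {
    for (i in 1:150) {
      s <- paste(sample(c("A", "C", "G", "T"), 10, replace = TRUE),
                 collapse = "")
      got <- scan_promoter(s, c("MCGCGB", "MCGTGT"))$count
      expect_equal(got, oracle_scan_count(s, c("MCGCGB", "MCGTGT")),
                   label = s)
    }
    # overlapping matches on a CG-rich run
    s <- "ACGCGCGCGT"
    expect_equal(scan_promoter(s, "MCGCGB")$count,
                 oracle_scan_count(s, "MCGCGB"))
  })
})

test_that("strand symmetry: a promoter and its reverse complement agree", {
  withr::with_seed(14, {
    for (i in 1:25) {
      s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE,
                        prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
      rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                  collapse = "")
      expect_equal(scan_promoter(s, CAMTA_MOTIFS)$count,
                   scan_promoter(rc, CAMTA_MOTIFS)$count)
    }
  })
})

test_that("extract_promoters follows strand conventions and truncation", {
  chrom <- paste(rep(c("A", "C", "G", "T"), 750), collapse = "")
  genome <- c(chr1 = chrom)
  plus <- gene_model("p", "chr1", "+", 1001, 2000, cbind(1001, 2000))
  minus <- gene_model("m", "chr1", "-", 1001, 2000, cbind(1001, 2000))
  short <- gene_model("s", "chr1", "+", 501, 900, cbind(501, 900))

  ps <- extract_promoters(genome, list(plus, minus, short), 1000)
  expect_equal(ps$entries[["p"]], substring(chrom, 1, 1000))
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA",
                                  substring(chrom, 2001, 3000)), "")[[1]]),
              collapse = "")
  expect_equal(ps$entries[["m"]], rc)
  expect_equal(nchar(ps$entries[["s"]]), 500L)
  expect_true(ps$truncated_flags[["s"]])
  expect_false(ps$truncated_flags[["p"]])
  expect_error(extract_promoters(genome, list(
    gene_model("x", "chrX", "+", 10, 20, cbind(10, 20))
  )), "chrX")
})

test_that("set_frequency: planted truth with AT-only background is exact", {
  gp <- gen_promoters(50, 300, planted_fraction = 0.4, gc = 0, seed = 10)
  expect_equal(sum(gp$planted), 20L)
  f <- set_frequency(gp$promoters)
  expect_equal(f$frequency, 0.4)
  all_planted <- gen_promoters(30, 200, planted_fraction = 1, gc = 0, seed = 2)
  expect_equal(set_frequency(all_planted$promoters)$frequency, 1)
  none <- gen_promoters(30, 200, planted_fraction = 0, gc = 0, seed = 2)
  expect_equal(set_frequency(none$promoters)$frequency, 0)
  expect_error(set_frequency(character()), "empty")
})

test_that("fisher_enrichment matches enumeration oracle and fisher.test", {
  f <- fisher_enrichment(3, 3, 0, 3)
  expect_equal(f$p_value, 0.1, tolerance = 1e-12)

  expect_equal(fisher_enrichment(5, 10, 10, 20)$p_value, 1)

  withr::with_seed(12, {
    for (i in 1:40) {
      na <- sample(1:25, 1); nb <- sample(1:25, 1)
      a <- sample(0:na, 1); b <- sample(0:nb, 1)
      got <- fisher_enrichment(a, na, b, nb)
      expect_equal(got$p_value, oracle_fisher_p(a, na, b, nb),
                   tolerance = 1e-9)
      ref <- stats::fisher.test(matrix(c(a, na - a, b, nb - b), 2))
      expect_equal(got$p_value, ref$p.value, tolerance = 1e-7)
    }
  })
  expect_error(fisher_enrichment(0, 0, 1, 2), "zero totals")
})

test_that("sample_control is seeded, disjoint from exclusions, exhaustive", {
  genes <- sprintf("g%03d", 1:100)
  excl <- genes[1:30]
  s1 <- sample_control(genes, excl, n = 50, seed = 4)
  s2 <- sample_control(genes, excl, n = 50, seed = 4)
  expect_identical(s1, s2)
  expect_length(intersect(s1, excl), 0)
  expect_length(s1, 50)
  expect_setequal(sample_control(genes, excl, n = 70, seed = 1),
                  setdiff(genes, excl))
  expect_error(sample_control(genes, excl, n = 71), "candidate")
})

test_that("motif_enrichment wires counts, frequency and test together", {
  g <- gen_promoters(60, 400, planted_fraction = 0.6, gc = 0, seed = 3)
  ctl <- gen_promoters(80, 400, planted_fraction = 0.1, gc = 0, seed = 4)
  res <- motif_enrichment(g$promoters, ctl$promoters, set_name = "pcoeg")
  expect_equal(res$frequency, 0.6)
  expect_equal(res$control_frequency, 0.1)
  expect_lt(res$p_value, 0.05)
  expect_gt(res$odds_ratio, 1)
})
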