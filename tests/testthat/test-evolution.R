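test_that("align_global: self-alignment, coverage arithmetic, brute-force score", {
  self <- align_global("MKVLA", "MKVLA")
  expect_equal(self$identity_pct, 100)
  expect_equal(self$coverage_pct, 100)

  part <- align_global("AAAA", "AAAAAAAA")
  expect_equal(part$coverage_pct, 50)

  expect_error(align_global("MK1A", "MKVA"), "invalid residue")

  withr::with_seed(17, {
    for (i in 1:12) {
      a <- paste(sample(c("A", "R", "W", "G", "K", "L"), sample(3:6, 1),
                        replace = TRUE), collapse = "")
      b <- paste(sample(c("A", "R", "W", "G", "K", "L"), sample(3:6, 1),
                        replace = TRUE), collapse = "")
      expect_equal(align_global(a, b)$score, oracle_best_score(a, b),
                   tolerance = 1e-9, label = paste(a, b))
    }
  })
})

test_that("detect_paralogs enforces strict >70/70 coverage and similarity", {
  base <- strrep("MKVLAWGERT", 10)
  prot <- c(p1 = base, p2 = base)
  expect_equal(nrow(detect_paralogs(prot)), 1L)

  # mutate ~45% of residues to dissimilar ones -> similarity well below 70
  withr::with_seed(5, {
    res <- strsplit(base, "")[[1]]
    idx <- sample(seq_along(res), 45)
    res[idx] <- vapply(res[idx], function(r) {
      std <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
      cand <- setdiff(std[oracle_blosum62[r, std] < 0], r)
      sample(cand, 1)
    }, character(1))
    mutated <- paste(res, collapse = "")
  })
  aln <- align_global(base, mutated)
  expect_lt(aln$similarity_pct, 70)
  expect_equal(nrow(detect_paralogs(c(a = base, b = mutated))), 0L)
  expect_error(detect_paralogs(c(a = base)), "at least 2")
})

test_that("rbh_orthologs returns mutual unique bests and logs ties", {
  a <- c(a1 = strrep("MKVLAWGERT", 5), a2 = strrep("FYPDNHQSCI", 5))
  b <- c(b1 = strrep("MKVLAWGERT", 5), b2 = strrep("FYPDNHQSCI", 5))
  res <- rbh_orthologs(a, b)
  expect_equal(nrow(res$pairs), 2L)
  expect_equal(res$pairs$id_b[match(c("a1", "a2"), res$pairs$id_a)],
               c("b1", "b2"))

  # duplicate identical target -> tie, no pair for a1
  b_tie <- c(b, b1dup = strrep("MKVLAWGERT", 5))
  res_tie <- rbh_orthologs(a["a1"], b_tie[c("b1", "b1dup")])
  expect_equal(nrow(res_tie$pairs), 0L)
  expect_true("a1" %in% res_tie$ties)
})

test_that("rbh recovers planted orthology across diverged sets", {
  cds <- lapply(1:4, function(i) random_nonstop_cds(120, seed = 100 + i))
  pairs <- lapply(seq_along(cds), function(i) {
    evolve_codon_pair(cds[[i]], 0.1, 0.4, seed = 200 + i)
  })
  set_a <- vapply(pairs, function(p) translate_cds(p$a), character(1))
  set_b <- vapply(pairs, function(p) translate_cds(p$b), character(1))
  names(set_a) <- paste0("A", 1:4)
  names(set_b) <- paste0("B", 1:4)
  res <- rbh_orthologs(set_a, set_b)
  expect_equal(nrow(res$pairs), 4L)
  expect_equal(res$pairs$id_b, sub("A", "B", res$pairs$id_a))
})

test_that("classify_duplication separates tandem from segmental", {
  mk <- function(id, chrom, start, end) {
    gene_model(id, chrom, "+", start, end, cbind(start, end))
  }
  models <- list(
    mk("g5", "chr5", 1e6, 1.01e6), mk("g13", "chr13", 2e6, 2.01e6),
    mk("near", "chr5", 1.03e6, 1.04e6), mk("far", "chr5", 1.51e6, 1.52e6)
  )
  expect_equal(classify_duplication(c("g5", "g13"), models)$dup_type,
               "segmental")
  tandem <- classify_duplication(c("g5", "near"), models)
  expect_equal(tandem$dup_type, "tandem")
  expect_equal(tandem$genomic_distance, 20000L)
  expect_equal(classify_duplication(c("g5", "far"), models)$dup_type,
               "segmental")
  expect_error(classify_duplication(c("g5", "nope"), models), "missing")
})

test_that("backtranslate_alignment maps protein gaps to codon gaps", {
  cds_a <- "ATGAAATTTGGG"   # M K F G
  cds_b <- "ATGTTTGGG"      # M F G
  aln <- align_global("MKFG", "MFG")
  cod <- backtranslate_alignment(aln, cds_a, cds_b)
  expect_equal(gsub("-", "", cod$a), cds_a)
  expect_equal(gsub("-", "", cod$b), cds_b)
  expect_equal(nchar(cod$a), nchar(cod$b))
  gap_pos <- regmatches(cod$b, gregexpr("-+", cod$b))[[1]]
  expect_equal(gap_pos, "---")

  # gapless alignment round-trips both CDS verbatim
  aln2 <- align_global("MKFG", "MKFG")
  cod2 <- backtranslate_alignment(aln2, cds_a, cds_a)
  expect_equal(cod2$a, cds_a)

  expect_error(backtranslate_alignment(aln2, cds_a, "ATGAAATTTCCC"),
               "translation mismatch.*codon 4")
})

test_that("kaks_ratio_and_selection reproduces printed ratio arithmetic", {
  r1 <- kaks_ratio_and_selection(0.1456, 0.4511)
  expect_equal(r1$ratio, 0.3228, tolerance = 0.005 / 0.3228)
  expect_equal(r1$selection, "purifying")

  expect_equal(kaks_ratio_and_selection(0.1472, 0.4030)$ratio, 0.3653,
               tolerance = 0.005 / 0.3653)

  expect_equal(kaks_ratio_and_selection(0.2, 0.2)$selection, "neutral")
  expect_equal(kaks_ratio_and_selection(0.3, 0.2)$selection, "positive")
  expect_equal(kaks_ratio_and_selection(0.1, 0)$selection, "undefined")
})

test_that("date_duplication is the Ks/(2 lambda) clock, linear in both", {
  expect_equal(date_duplication(0.3907), 13.02, tolerance = 0.005)
  expect_equal(date_duplication(0.4104), 13.68, tolerance = 0.005)
  expect_equal(date_duplication(0), 0)
  expect_error(date_duplication(0.1, 0), "lambda")

  withr::with_seed(2, {
    ks <- runif(20, 0, 2)
    expect_equal(date_duplication(2 * ks), 2 * date_duplication(ks))
    expect_equal(date_duplication(ks, 3e-8), date_duplication(ks) / 2)
  })
})

test_that("gene_structure_signature groups by intron count and exon lengths", {
  mk <- function(id, lens, gap = 100L) {
    starts <- cumsum(c(1L, head(lens, -1) + gap))
    gene_model(id, "chr1", "+", 1L, starts[length(lens)] + lens[length(lens)],
               cbind(starts, starts + lens - 1L))
  }
  sig <- gene_structure_signature(list(
    mk("a", c(100L, 200L, 300L)),
    mk("b", c(100L, 200L, 300L)),
    mk("c", c(110L, 210L, 310L)),     # within 20% of a/b
    mk("d", c(100L, 200L, 300L, 50L)) # different intron count
  ))
  expect_equal(sig$n_introns, c(2L, 2L, 2L, 3L))
  expect_equal(sig$group[1], sig$group[2])
  expect_equal(sig$group[1], sig$group[3])
  expect_false(sig$group[1] == sig$group[4])

  empty <- gene_structure_signature(list())
  expect_equal(nrow(empty), 0L)
})
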