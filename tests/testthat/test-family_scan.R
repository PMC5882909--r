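test_that("scan_consensus finds the IQ motif and handles edge cases", {
  hits <- scan_consensus(protein_record("p", "AAIQAAARGAAARAA"), "IQ")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 3L)
  expect_equal(hits$end, 13L)
  expect_equal(hits$matched_text, "IQAAARGAAAR")

  expect_equal(nrow(scan_consensus(protein_record("p", "AAAA"), "IQ")), 0L)
  expect_equal(nrow(scan_consensus(protein_record("p", ""), "IQ")), 0L)
  expect_error(scan_consensus("AAAA", "NOPE"), "unknown pattern")
})

test_that("CaMBD consensus matches a hand-built instance exactly once", {
  # W X V XX [LVI] X K XX L R W R X [KR] XXX [FL] R X
  inst <- "WAVAALAKAALRWRAKAAAFRA"
  seq <- paste0("MA", inst, "G")
  hits <- scan_consensus(protein_record("p", seq), "CaMBD")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$matched_text, inst)
  # breaking a literal anchor kills the match
  broken <- sub("RWR", "RAR", seq)
  expect_equal(nrow(scan_consensus(protein_record("p", broken), "CaMBD")), 0L)
})

test_that("scan hits are non-overlapping, sorted and slice-consistent", {
  seq <- paste(rep("IQAAARGAAAR", 4), collapse = "AA")
  pr <- protein_record("p", seq)
  hits <- scan_consensus(pr, "IQ")
  expect_equal(nrow(hits), 4L)
  expect_true(all(diff(hits$start) > 0))
  expect_true(all(hits$start[-1] > hits$end[-nrow(hits)]))
  expect_equal(hits$matched_text,
               substring(seq, hits$start, hits$end))
})

test_that("classify_architecture applies the CG-1 + CaM-feature rule", {
  mk <- function(domains) {
    data.frame(domain = domains, start = seq_along(domains) * 50L,
               end = seq_along(domains) * 50L + 10L,
               matched_text = character(length(domains)),
               stringsAsFactors = FALSE)
  }
  pr <- protein_record("p", paste(rep("A", 600), collapse = ""))

  full <- classify_architecture(mk(c("CG1", "TIG", "ANK", "IQ", "IQ", "CaMBD")), pr)
  expect_true(full$is_camta)
  expect_equal(full$tig_type, "TIG")
  expect_equal(full$iq_count, 2L)

  nontig <- classify_architecture(mk(c("CG1", "ANK", "IQ", "CaMBD")), pr)
  expect_true(nontig$is_camta)
  expect_equal(nontig$tig_type, "non-TIG")

  none <- classify_architecture(mk(character()), pr)
  expect_false(none$is_camta)
  expect_equal(none$tig_type, "n/a")

  # CaMBD alone (no CG-1) is not a CAMTA
  expect_false(classify_architecture(mk(c("TIG", "CaMBD")), pr)$is_camta)
})

test_that("compute_mw matches residue-table arithmetic and is additive", {
  expect_equal(compute_mw("G"), 75.07, tolerance = 1e-4)
  expect_equal(compute_mw("GG"), 132.12, tolerance = 1e-4)
  expect_error(compute_mw(""), "empty")
  expect_error(compute_mw(protein_record("p", "GXG")), "position 2")

  withr::with_seed(7, {
    for (i in 1:20) {
      a <- paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "W", "Y"),
                        sample(1:30, 1), replace = TRUE), collapse = "")
      b <- paste(sample(c("H", "I", "L", "K", "M", "F", "P", "S", "T", "V"),
                        sample(1:30, 1), replace = TRUE), collapse = "")
      expect_equal(compute_mw(paste0(a, b)),
                   compute_mw(a) + compute_mw(b) - 18.01524,
                   tolerance = 1e-9)
    }
  })
})

test_that("compute_pi satisfies the charge-root oracle and is monotone", {
  expect_lt(abs(net_charge("AA", compute_pi("AA"))), 1e-4)
  expect_gt(compute_pi(strrep("K", 10)), compute_pi(strrep("D", 10)))

  withr::with_seed(11, {
    for (i in 1:25) {
      pep <- paste(sample(c("A", "D", "E", "K", "R", "H", "C", "Y", "G", "S"),
                          sample(2:40, 1), replace = TRUE), collapse = "")
      pi <- compute_pi(pep)
      expect_lt(abs(net_charge(pep, pi)), 1e-4)
      expect_gt(net_charge(pep, 0), 0)
      expect_lt(net_charge(pep, 14), 0)
      # strictly decreasing across a pH grid
      grid <- vapply(seq(0, 14, by = 0.5), net_charge, numeric(1),
                     protein = pep)
      expect_true(all(diff(grid) < 0))
    }
  })
})

test_that("hydrophobic_moment equals the direct complex-sum oracle", {
  one <- hydrophobic_moment("ILKA", start = 2, window = 1)
  expect_equal(one$hydrophobic_moment, 1.06, tolerance = 1e-12)

  const <- hydrophobic_moment(strrep("V", 20), 1, window = 18)
  expect_equal(const$mean_hydrophobicity, 1.08, tolerance = 1e-12)
  expect_equal(const$wheel_classes, rep("hydrophobic", 18))

  scale <- c(A = 0.62, R = -2.53, N = -0.78, D = -0.90, C = 0.29, Q = -0.85,
             E = -0.74, G = 0.48, H = -0.40, I = 1.38, L = 1.06, K = -1.50,
             M = 0.64, F = 1.19, P = 0.12, S = -0.18, T = -0.05, W = 0.81,
             Y = 0.26, V = 1.08)
  withr::with_seed(3, {
    for (i in 1:20) {
      pep <- paste(sample(names(scale), 25, replace = TRUE), collapse = "")
      ws <- hydrophobic_moment(pep, start = 4, window = 18)
      h <- scale[strsplit(substr(pep, 4, 21), "")[[1]]]
      z <- sum(h * exp(1i * seq_len(18) * 100 * pi / 180))
      expect_equal(ws$hydrophobic_moment, Mod(z) / 18, tolerance = 1e-12)
      expect_gte(ws$hydrophobic_moment, 0)
    }
  })
  expect_error(hydrophobic_moment("MKVLA", 1, window = 18), "exceeds")
})

test_that("a planted amphipathic helix is called, a poly-V window is not", {
  # alternating hydrophobic/charged faces with delta = 100 degrees
  helix <- "VLKKLVESLFKKWLRV"
  mu <- hydrophobic_moment(paste0("AA", helix), 3, window = 16)
  expect_true(mu$amphipathic)
  expect_false(hydrophobic_moment(strrep("V", 18), 1)$amphipathic)
})

test_that("intron counts derive from exon counts, order-invariant", {
  models <- make_test_models()
  expect_equal(intron_counts(models), c(gA = 2L, gB = 0L, gC = 1L))

  starts13 <- seq(1L, by = 100L, length.out = 13L)
  g13 <- gene_model("g13", "chr1", "+", 1, 1250,
                    cbind(starts13, starts13 + 49L))
  expect_equal(unname(intron_counts(list(g13))), 12L)

  shuffled <- gene_model("gS", "chr1", "+", 1001, 2000,
                         cbind(c(1801, 1001, 1401), c(2000, 1200, 1600)))
  expect_equal(unname(intron_counts(list(shuffled))), 2L)

  expect_error(
    gene_model("bad", "chr1", "+", 1, 100, cbind(c(1, 40), c(50, 90))),
    "overlapping"
  )
})

test_that("NLS rule finds bipartite basic clusters inside planted CG-1", {
  b <- gen_annotated_genome(sim_config(seed = 21, n_genes = 3),
                            n_camta_tig = 1, n_camta_non_tig = 0)
  pr <- protein_record("g1", b$proteins[[1]])
  cg1 <- scan_consensus(pr, "CG1")
  nls <- scan_consensus(pr, "NLS")
  expect_equal(nrow(cg1), 1L)
  expect_true(any(nls$start >= cg1$start & nls$end <= cg1$end))
})
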