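test_that("sim_config validates proportions and rates", {
  expect_error(sim_config(planted_motif_fraction = 1.2), "planted_motif_fraction")
  expect_error(sim_config(target_ka = -0.1), "target_ka")
  expect_error(sim_config(trait_r = 2), "trait_r")
  cfg <- sim_config()
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$promoter_length, 1000L)
})

test_that("gen_annotated_genome: empty case, determinism, capacity error", {
  empty <- gen_annotated_genome(sim_config(n_genes = 0, chrom_length = 5000))
  expect_length(empty$models, 0)
  expect_equal(nchar(empty$genome[["chr1"]]), 5000L)

  b1 <- gen_annotated_genome(sim_config(seed = 1, n_genes = 5))
  b2 <- gen_annotated_genome(sim_config(seed = 1, n_genes = 5))
  expect_identical(b1, b2)
  b3 <- gen_annotated_genome(sim_config(seed = 2, n_genes = 5))
  expect_false(identical(b1$genome, b3$genome))

  expect_error(
    gen_annotated_genome(sim_config(n_genes = 5, chrom_length = 8000)),
    "cannot host"
  )
})

test_that("generated gene models are GFF3-consistent and CDS legal", {
  b <- gen_annotated_genome(sim_config(seed = 8, n_genes = 6))
  for (i in seq_along(b$models)) {
    gm <- b$models[[i]]
    expect_true(all(gm$exons[, 1] >= gm$start & gm$exons[, 2] <= gm$end))
    cds <- b$cds[[i]]
    expect_equal(nchar(cds) %% 3, 0)
    expect_equal(translate_cds(cds), b$proteins[[i]])  # errors on internal stop
    expect_equal(splice_cds(b$genome, gm), cds)
  }
})

test_that("planted architectures are recovered with zero errors", {
  b <- gen_annotated_genome(sim_config(seed = 15, n_genes = 8),
                            n_camta_tig = 3, n_camta_non_tig = 2)
  arch <- lapply(names(b$proteins), function(id) {
    pr <- protein_record(id, b$proteins[[id]])
    classify_architecture(scan_all_domains(pr), pr)
  })
  is_camta <- vapply(arch, `[[`, logical(1), "is_camta")
  tig <- vapply(arch, `[[`, character(1), "tig_type")
  iq <- vapply(arch, `[[`, integer(1), "iq_count")
  expect_equal(is_camta, b$truth$planted_camta)
  expect_equal(tig == "TIG", b$truth$planted_tig)
  expect_equal(iq[b$truth$planted_camta], b$truth$n_iq[b$truth$planted_camta])
  expect_equal(sum(tig == "TIG"), 3L)
  expect_equal(sum(tig == "non-TIG"), 2L)
})

test_that("evolve_codon_pair: zero-divergence and ka-only-zero cases", {
  anc <- random_nonstop_cds(40, seed = 3)
  p0 <- evolve_codon_pair(anc, 0, 0, seed = 5)
  expect_equal(p0$a, anc)
  expect_equal(p0$b, anc)
  expect_false(p0$flagged)

  # no non-synonymous proposals: descendants translate identically to the
  # ancestor, so realized protein divergence is zero by construction
  pk <- evolve_codon_pair(random_nonstop_cds(30, seed = 4), 0, 0.3, seed = 6)
  expect_equal(translate_cds(pk$a), translate_cds(pk$ancestor))
  expect_equal(translate_cds(pk$b), translate_cds(pk$ancestor))
  est <- nei_gojobori(list(a = pk$a, b = pk$b))
  expect_equal(est$Ka, 0)
  expect_gt(est$Ks, 0)

  expect_error(evolve_codon_pair("ATGA", 0.1, 0.1), "divisible")
  expect_error(evolve_codon_pair("ATGTAAAAA", 0.1, 0.1), "stop")
})

test_that("evolve_codon_pair is deterministic and flags saturation", {
  anc <- random_nonstop_cds(60, seed = 7)
  a1 <- evolve_codon_pair(anc, 0.1, 0.4, seed = 11)
  a2 <- evolve_codon_pair(anc, 0.1, 0.4, seed = 11)
  expect_identical(a1, a2)

  sat <- evolve_codon_pair(random_nonstop_cds(200, seed = 8), 0.1, 30,
                           seed = 12)
  expect_true(sat$flagged)
})

test_that("descendants never contain internal stop codons", {
  for (seed in 1:10) {
    p <- evolve_codon_pair(random_nonstop_cds(80, seed = seed), 0.5, 1.5,
                           seed = seed)
    expect_silent(translate_cds(p$a))
    expect_silent(translate_cds(p$b))
  }
})

test_that("gen_promoters label bookkeeping is exact", {
  for (frac in c(0, 0.29, 0.41, 1)) {
    gp <- gen_promoters(137, 250, planted_fraction = frac, gc = 0.35,
                        seed = 17)
    expect_equal(sum(gp$planted), round(137 * frac))
    expect_equal(length(gp$promoters), 137L)
    expect_true(all(nchar(gp$promoters) == 250L))
  }
  # every planted promoter scans positive (labels record planting, and the
  # planted instance guarantees >= 1 match)
  gp <- gen_promoters(60, 300, planted_fraction = 0.5, gc = 0.35, seed = 18)
  hits <- vapply(gp$promoters, function(s) scan_promoter(s)$count > 0,
                 logical(1))
  expect_true(all(hits[gp$planted]))
  expect_error(gen_promoters(5, 4, motifs = "MCGCGB"), "longer")
  expect_identical(gen_promoters(20, 100, seed = 9),
                   gen_promoters(20, 100, seed = 9))
})

test_that("gen_expression: non-negativity, memberships, determinism", {
  ge <- gen_expression(200, 5, 30, 20, noise_sd = 0.05, seed = 19)
  expect_true(all(ge$matrix >= 0))
  expect_equal(dim(ge$matrix), c(200L, 5L))
  expect_equal(table(ge$truth$module)[["positive"]], 30L)
  expect_equal(table(ge$truth$module)[["negative"]], 20L)
  expect_identical(ge, gen_expression(200, 5, 30, 20, noise_sd = 0.05,
                                      seed = 19))
  expect_error(gen_expression(10, 2, 2, 2), "n_stages")
  expect_error(gen_expression(10, 5, 8, 8), "modules")
})

test_that("gen_trait_table: exact degenerate case and convergence", {
  tt1 <- gen_trait_table(50, trait_r = 1, seed = 20)
  expect_equal(cor(1 / tt1$dct, tt1$trait), 1, tolerance = 1e-12)

  ttm <- gen_trait_table(50, trait_r = -1, seed = 20)
  expect_equal(cor(1 / ttm$dct, ttm$trait), -1, tolerance = 1e-12)

  expect_equal(nrow(gen_trait_table(3, 0.5, seed = 1)), 3L)
  expect_error(gen_trait_table(2, 0.5), ">= 3")
  expect_true(all(gen_trait_table(500, 0.63, seed = 2)$dct >= 2))

  for (r in c(-0.5, 0, 0.63)) {
    tt <- gen_trait_table(10000, trait_r = r, seed = 23)
    expect_lt(abs(cor(1 / tt$dct, tt$trait) - r), 0.02,
              label = paste("trait_r", r, "recovery error"))
  }
})
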