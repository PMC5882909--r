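# Synthetic-data generators with known ground truth.
#
# Every downstream stage gets a parameter-recovery or planted-signal test
# from these: annotated genomes with planted CAMTA architectures, codon pairs
# diverged at controlled Ka/Ks, promoter sets with a planted motif fraction,
# expression matrices with correlated/anti-correlated modules around a focal
# gene, and genotype trait tables with a controlled correlation to a 1/dCt
# expression proxy. All generators are byte-deterministic given (config, seed).

#' Simulation configuration
#'
#' Defaults state the emulated world: five fiber developmental stages,
#' 1000-bp promoters, AT-rich (35% GC) cotton-like promoter composition,
#' divergence targets Ka = 0.1 / Ks = 0.4 matching the magnitude of the
#' duplicated-pair estimates, and a 0.63 expression-trait correlation.
#'
#' @param seed Integer seed.
#' @param n_genes Number of genes on the simulated chromosome.
#' @param chrom_length Chromosome length (bp).
#' @param promoter_length Upstream promoter length (bp).
#' @param planted_motif_fraction Fraction of promoters with a planted motif.
#' @param gc_content Background GC proportion in (0, 1).
#' @param target_ka,target_ks Divergence targets (substitutions per site).
#' @param n_stages Number of expression stages (>= 3).
#' @param focal_module_size Positively co-expressed module size.
#' @param noise_sd Expression noise standard deviation.
#' @param trait_r Target Pearson correlation of trait with 1/dCt.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 12L, chrom_length = 120000L,
                       promoter_length = 1000L, planted_motif_fraction = 0.3,
                       gc_content = 0.35, target_ka = 0.1, target_ks = 0.4,
                       n_stages = 5L, focal_module_size = 60L,
                       noise_sd = 0.05, trait_r = 0.63) {
  assert_scalar_number(planted_motif_fraction, "planted_motif_fraction", 0, 1)
  assert_scalar_number(gc_content, "gc_content", 0, 1)
  assert_scalar_number(target_ka, "target_ka", 0)
  assert_scalar_number(target_ks, "target_ks", 0)
  assert_scalar_number(trait_r, "trait_r", -1, 1)
  assert_scalar_number(n_stages, "n_stages", 0)
  if (n_genes < 0) stop("n_genes must be >= 0", call. = FALSE)
  structure(
    list(
      seed = as.integer(seed), n_genes = as.integer(n_genes),
      chrom_length = as.integer(chrom_length),
      promoter_length = as.integer(promoter_length),
      planted_motif_fraction = planted_motif_fraction,
      gc_content = gc_content, target_ka = target_ka, target_ks = target_ks,
      n_stages = as.integer(n_stages),
      focal_module_size = as.integer(focal_module_size),
      noise_sd = noise_sd, trait_r = trait_r
    ),
    class = "sim_config"
  )
}

random_dna <- function(n, gc) {
  paste(sample(DNA_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Residues used for unconstrained consensus positions and linkers: non-basic
# so planted basic-residue clusters (the NLS) stay where they were planted.
SAFE_AA <- setdiff(AA_STANDARD, c("K", "R"))

sample_consensus_instance <- function(pattern) {
  tokens <- parse_consensus(pattern)
  paste(unlist(lapply(tokens, function(tk) {
    cls <- if (length(tk$class) == 20L) SAFE_AA else tk$class
    sample(cls, tk$rep, replace = TRUE)
  })), collapse = "")
}

synth_camta_protein <- function(length_aa = 260L, tig = TRUE, n_iq = 2L) {
  linker <- function(n) paste(sample(SAFE_AA, n, replace = TRUE), collapse = "")
  parts <- c(
    linker(5),
    sample_consensus_instance(CONSENSUS_PATTERNS[["CG1"]]),
    linker(12),
    if (tig) c(sample_consensus_instance(CONSENSUS_PATTERNS[["TIG"]]), linker(10)),
    sample_consensus_instance(CONSENSUS_PATTERNS[["ANK"]]),
    linker(10)
  )
  for (i in seq_len(n_iq)) {
    parts <- c(parts, sample_consensus_instance(CONSENSUS_PATTERNS[["IQ"]]),
               linker(6))
  }
  parts <- c(parts, sample_consensus_instance(CONSENSUS_PATTERNS[["CaMBD"]]))
  core <- paste(parts, collapse = "")
  pad <- length_aa - nchar(core)
  if (pad > 0) core <- paste0(core, linker(pad))
  core
}

aa_to_codons_table <- function() {
  if (is.null(.camta_cache$aa2codon)) {
    gc <- genetic_code()
    .camta_cache$aa2codon <- split(names(gc), gc)
  }
  .camta_cache$aa2codon
}

reverse_translate <- function(protein) {
  tab <- aa_to_codons_table()
  res <- strsplit(protein, "")[[1]]
  paste(vapply(res, function(a) sample(tab[[a]], 1L)[[1]], character(1)),
        collapse = "")
}

#' Generate an annotated genome with planted CAMTA architectures
#'
#' Lays out `n_genes` multi-exon genes on one chromosome with
#' `promoter_length` bp of intergenic background on both sides of every
#' gene. The first `n_camta_tig` proteins carry the full CAMTA architecture
#' (CG-1, TIG, ankyrin, IQ x `n_iq`, CaMBD in order), the next
#' `n_camta_non_tig` omit the TIG segment, and the rest are random
#' background proteins. CDS are uniform-synonymous reverse translations of
#' the proteins (so translation round-trips exactly) and are split into
#' exons with random introns between them.
#'
#' @param config A [sim_config()].
#' @param n_camta_tig,n_camta_non_tig Planted architecture counts.
#' @param n_iq IQ motifs per planted CAMTA (1-3).
#' @param protein_length Planted/background protein length (aa).
#' @return List with `genome` (named character), `models` (list of
#'   [gene_model()]), `cds`, `proteins` (named character vectors) and
#'   `truth` (data frame id, planted_camta, planted_tig, n_iq).
#' @export
gen_annotated_genome <- function(config, n_camta_tig = 2L,
                                 n_camta_non_tig = 1L, n_iq = 2L,
                                 protein_length = 260L) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  if (n_camta_tig + n_camta_non_tig > n && n > 0L) {
    stop("more planted CAMTAs than genes", call. = FALSE)
  }
  with_seed(config$seed, {
    if (n == 0L) {
      return(list(
        genome = c(chr1 = random_dna(config$chrom_length, config$gc_content)),
        models = list(), cds = character(), proteins = character(),
        truth = data.frame(id = character(), planted_camta = logical(),
                           planted_tig = logical(), n_iq = integer())
      ))
    }
    ids <- sprintf("gene%03d", seq_len(n))
    kind <- rep("background", n)
    if (n_camta_tig > 0L) kind[seq_len(n_camta_tig)] <- "tig"
    if (n_camta_non_tig > 0L) {
      kind[n_camta_tig + seq_len(n_camta_non_tig)] <- "non_tig"
    }
    proteins <- vapply(kind, function(k) {
      switch(k,
        tig = synth_camta_protein(protein_length, tig = TRUE, n_iq = n_iq),
        non_tig = synth_camta_protein(protein_length, tig = FALSE, n_iq = n_iq),
        background = paste(sample(SAFE_AA, protein_length, replace = TRUE),
                           collapse = "")
      )
    }, character(1))
    names(proteins) <- ids
    cds <- vapply(proteins, reverse_translate, character(1))

    models <- vector("list", n)
    segments <- character()
    cursor <- 1L
    pl <- config$promoter_length
    for (i in seq_len(n)) {
      n_exons <- sample(11:14, 1L)
      clen <- nchar(cds[[i]])
      cuts <- sort(sample(seq(3L, clen - 3L), n_exons - 1L))
      exon_lens <- diff(c(0L, cuts, clen))
      intron_seqs <- replicate(n_exons - 1L,
                               random_dna(sample(60:120, 1L), config$gc_content))
      exon_seqs <- substring(cds[[i]], c(1L, cuts + 1L), c(cuts, clen))
      gene_seq <- exon_seqs[1]
      offsets <- matrix(0L, n_exons, 2)
      offsets[1, ] <- c(1L, exon_lens[1])
      for (k in seq_len(n_exons - 1L)) {
        gene_seq <- paste0(gene_seq, intron_seqs[k], exon_seqs[k + 1L])
        s <- offsets[k, 2] + nchar(intron_seqs[k]) + 1L
        offsets[k + 1L, ] <- c(s, s + exon_lens[k + 1L] - 1L)
      }
      glen <- nchar(gene_seq)
      start <- cursor + pl
      end <- start + glen - 1L
      if (end + pl > config$chrom_length) {
        stop("chrom_length ", config$chrom_length, " cannot host ", n,
             " genes with ", pl, " bp promoters (need > ", end + pl, " bp)",
             call. = FALSE)
      }
      strand <- sample(c("+", "-"), 1L)
      exons <- if (strand == "+") {
        cbind(start + offsets[, 1] - 1L, start + offsets[, 2] - 1L)
      } else {
        cbind(end - offsets[, 2] + 1L, end - offsets[, 1] + 1L)
      }
      models[[i]] <- gene_model(
        ids[i], "chr1", strand, start, end,
        exons[order(exons[, 1]), , drop = FALSE]
      )
      segments <- c(segments, random_dna(start - cursor, config$gc_content),
                    if (strand == "+") gene_seq else revcomp(gene_seq))
      cursor <- end + 1L
    }
    segments <- c(segments,
                  random_dna(config$chrom_length - cursor + 1L,
                             config$gc_content))
    genome <- c(chr1 = paste(segments, collapse = ""))
    stopifnot(nchar(genome) == config$chrom_length)
    list(
      genome = genome, models = models, cds = cds, proteins = proteins,
      truth = data.frame(
        id = ids, planted_camta = kind != "background",
        planted_tig = kind == "tig",
        n_iq = ifelse(kind == "background", 0L, n_iq),
        stringsAsFactors = FALSE
      )
    )
  })
}

# One lineage: per-position Poisson event counts at the ancestor's NG86 site
# fractions, jump-chain moves within the synonymous / non-synonymous (non-stop)
# alternative sets. Site classes are frozen on the ancestor (documented small
# bias at extreme rates).
evolve_lineage <- function(codons, ka_half, ks_half) {
  gc <- genetic_code()
  frac <- codon_syn_fractions()
  f <- frac[codons, , drop = FALSE]
  n_syn <- matrix(rpois(length(f), ks_half * f), ncol = 3)
  n_non <- matrix(rpois(length(f), ka_half * (1 - f)), ncol = 3)
  hit <- which(rowSums(n_syn + n_non) > 0L)
  for (i in hit) {
    ev <- unlist(lapply(1:3, function(pos) {
      c(rep(paste0("s", pos), n_syn[i, pos]),
        rep(paste0("n", pos), n_non[i, pos]))
    }))
    ev <- sample(ev)
    cur <- codons[i]
    for (e in ev) {
      pos <- as.integer(substr(e, 2, 2))
      nb <- codon_neighbours(cur, pos)
      nb <- nb[gc[nb] != "*"]
      alt <- if (substr(e, 1, 1) == "s") {
        nb[gc[nb] == gc[[cur]]]
      } else {
        nb[gc[nb] != gc[[cur]]]
      }
      if (length(alt)) cur <- sample(alt, 1L)[[1]]
    }
    codons[i] <- cur
  }
  codons
}

#' Evolve a pair of descendants from an ancestral CDS
#'
#' Substitutions are placed independently on synonymous and non-synonymous
#' sites (NG86 fractional site classes on the ancestor) so that the expected
#' pairwise per-site divergence between the two descendants equals
#' `target_ka` / `target_ks` (each lineage receives half). Proposals that
#' would create a stop codon are rejected and redrawn. If the realized
#' proportions saturate the Jukes-Cantor correction (p >= 3/4) the result is
#' flagged, not silently dropped.
#'
#' @param cds Ancestral CDS (length divisible by 3, no internal stops).
#' @param target_ka,target_ks Target divergence (substitutions per site).
#' @param seed Seed.
#' @return List with descendants `a`, `b`, the `ancestor`, and `flagged`.
#' @export
evolve_codon_pair <- function(cds, target_ka, target_ks, seed = 1L) {
  cds <- toupper(cds)
  translate_cds(cds)  # validates: divisible by 3, no internal stops
  assert_scalar_number(target_ka, "target_ka", 0)
  assert_scalar_number(target_ks, "target_ks", 0)
  codons <- split_codons(cds)
  with_seed(seed, {
    a <- paste(evolve_lineage(codons, target_ka / 2, target_ks / 2),
               collapse = "")
    b <- paste(evolve_lineage(codons, target_ka / 2, target_ks / 2),
               collapse = "")
    est <- nei_gojobori(list(a = a, b = b))
    list(a = a, b = b, ancestor = cds,
         flagged = is.na(est$Ka) || is.na(est$Ks))
  })
}

#' Generate promoters with a planted motif fraction
#'
#' Exactly `round(n * planted_fraction)` promoters receive one planted
#' instance (a uniformly chosen member of a uniformly chosen motif's
#' expansion set at a uniform position). Background is i.i.d. per base with
#' symmetric GC split, and may create additional chance matches: labels
#' record planting, not total matches.
#'
#' @param n Number of promoters.
#' @param length Promoter length (bp).
#' @param motifs IUPAC motif strings.
#' @param planted_fraction Proportion in [0, 1].
#' @param gc Background GC content.
#' @param seed Seed.
#' @return List with `promoters` (named character) and `planted` (named
#'   logical ground-truth labels).
#' @export
gen_promoters <- function(n, length = 1000L, motifs = CAMTA_MOTIFS,
                          planted_fraction = 0.3, gc = 0.35, seed = 1L) {
  assert_scalar_number(planted_fraction, "planted_fraction", 0, 1)
  matchers <- as_matchers(motifs)
  if (any(vapply(matchers, `[[`, integer(1), "length") > length)) {
    stop("motif longer than promoter", call. = FALSE)
  }
  with_seed(seed, {
    proms <- vapply(seq_len(n), function(i) random_dna(length, gc),
                    character(1))
    names(proms) <- sprintf("prom%04d", seq_len(n))
    planted <- logical(n)
    names(planted) <- names(proms)
    n_plant <- round(n * planted_fraction)
    if (n_plant > 0L) {
      idx <- sample.int(n, n_plant)
      for (i in idx) {
        m <- matchers[[sample.int(length(matchers), 1L)]]
        inst <- sample(m$expansion, 1L)
        pos <- sample.int(length - m$length + 1L, 1L)
        substr(proms[i], pos, pos + m$length - 1L) <- inst
        planted[i] <- TRUE
      }
    }
    list(promoters = proms, planted = planted)
  })
}

#' Generate an expression matrix with planted co-expression modules
#'
#' The first gene is the focal gene. Module genes are affine transforms of
#' the focal profile plus Gaussian noise on the log2(FPKM + 1) scale -- the
#' scale on which the co-expression network is built -- with positive slope
#' for the positive module and negative slope (level-shifted to stay
#' non-negative) for the anti-module; background genes are independent.
#' Values are mapped back through 2^y - 1 and clipped at 0, so with
#' `noise_sd = 0` module correlations with the focal profile are exactly
#' +/-1 after [log2_transform()].
#'
#' @param n_genes Total genes (>= 1 + module sizes).
#' @param n_stages Stages (>= 3); 5 stages are labelled as DPA time points.
#' @param focal_module_size,anti_module_size Planted module sizes.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Seed.
#' @return List with `matrix` (genes x stages FPKM), `focal` (gene id) and
#'   `truth` (data frame gene, module in focal/positive/negative/background).
#' @export
gen_expression <- function(n_genes, n_stages = 5L, focal_module_size = 60L,
                           anti_module_size = 40L, noise_sd = 0.05,
                           seed = 1L) {
  if (n_stages < 3L) stop("n_stages must be >= 3", call. = FALSE)
  if (1L + focal_module_size + anti_module_size > n_genes) {
    stop("modules larger than gene count", call. = FALSE)
  }
  with_seed(seed, {
    ids <- sprintf("gene%05d", seq_len(n_genes))
    module <- rep("background", n_genes)
    module[1] <- "focal"
    if (focal_module_size > 0L) module[1L + seq_len(focal_module_size)] <- "positive"
    if (anti_module_size > 0L) {
      module[1L + focal_module_size + seq_len(anti_module_size)] <- "negative"
    }
    f <- stats::rlnorm(n_stages, meanlog = 2, sdlog = 0.6)
    lf <- log2(f + 1)
    m <- matrix(0, n_genes, n_stages)
    m[1, ] <- f
    for (i in seq_len(n_genes)[-1]) {
      lg <- switch(module[i],
        positive = runif(1, 0.2, 2) + runif(1, 0.5, 2) * lf +
          rnorm(n_stages, 0, noise_sd),
        negative = {
          b <- runif(1, 0.5, 2)
          b * max(lf) + runif(1, 0.5, 2) - b * lf + rnorm(n_stages, 0, noise_sd)
        },
        background = NULL
      )
      m[i, ] <- if (is.null(lg)) {
        stats::rlnorm(n_stages, meanlog = 1.5, sdlog = 0.7)
      } else {
        2^lg - 1
      }
    }
    m[m < 0] <- 0
    rownames(m) <- ids
    colnames(m) <- if (n_stages == 5L) {
      paste0("dpa", c(0, 5, 10, 20, 25))
    } else {
      paste0("stage", seq_len(n_stages))
    }
    list(
      matrix = m, focal = ids[1],
      truth = data.frame(gene = ids, module = module, stringsAsFactors = FALSE)
    )
  })
}

#' Generate a genotype trait table with controlled expression correlation
#'
#' dCt values are drawn from a truncated Normal(8, 1.5) (>= 2, a plausible
#' qRT-PCR range against a Ubiquitin reference); the trait is an affine blend
#' of the standardized 1/dCt proxy and independent noise with population
#' correlation `trait_r`, scaled to fiber-strength-like units. Sample r
#' converges to `trait_r` as n grows and equals it exactly at |trait_r| = 1.
#'
#' @param n_genotypes Number of genotypes (>= 3).
#' @param trait_r Target correlation in [-1, 1].
#' @param seed Seed.
#' @return Data frame with `genotype`, `dct`, `trait`.
#' @export
gen_trait_table <- function(n_genotypes, trait_r = 0.63, seed = 1L) {
  assert_scalar_number(trait_r, "trait_r", -1, 1)
  if (n_genotypes < 3L) stop("need >= 3 genotypes", call. = FALSE)
  with_seed(seed, {
    dct <- rnorm(n_genotypes, 8, 1.5)
    while (any(dct < 2)) {
      dct[dct < 2] <- rnorm(sum(dct < 2), 8, 1.5)
    }
    proxy <- 1 / dct
    z <- rnorm(n_genotypes)
    std <- function(v) (v - mean(v)) / stats::sd(v)
    t_std <- trait_r * std(proxy) + sqrt(1 - trait_r^2) * std(z)
    data.frame(
      genotype = sprintf("geno%04d", seq_len(n_genotypes)),
      dct = dct,
      trait = 25 + 3 * t_std,
      stringsAsFactors = FALSE
    )
  })
}
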