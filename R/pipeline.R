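# Pipeline orchestration: stage runners, run manifests and the CLI front-end.
# Every stage default equals the published analysis values: r thresholds
# 0.95/-0.95, 1000-bp promoters, motifs MCGCGB+MCGTGT, lambda = 1.5e-8,
# control n = 700. All randomness flows from one top-level seed, expanded
# per stage deterministically.

write_manifest <- function(path, stage, inputs, params, seed) {
  manifest <- list(
    stage = stage, inputs = inputs, params = params, seed = seed,
    package = "camtakit",
    version = as.character(packageVersion("camtakit"))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Simulate a full input bundle
#'
#' Writes genome FASTA, gene models GFF3, CDS/protein FASTA, a diverged CDS
#' pair for the Ka/Ks stage, an expression matrix, Ct and trait tables, and
#' plain-TSV ground-truth files, plus a machine-readable run manifest.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param n_expr_genes Genes in the simulated expression matrix.
#' @param n_genotypes Genotypes in the trait table.
#' @return Invisibly, the named list of written paths.
#' @export
run_simulate <- function(config, out_dir, n_expr_genes = 500L,
                         n_genotypes = 67L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  bundle <- gen_annotated_genome(config)
  write_fasta(bundle$genome, p("genome.fa"), "DNA")
  write_gff3(bundle$models, p("genes.gff3"))
  write_fasta(bundle$cds, p("cds.fa"), "DNA")
  write_fasta(bundle$proteins, p("proteins.fa"), "AA")
  write_tsv(bundle$truth, p("truth_genes.tsv"))

  if (length(bundle$cds)) {
    pair <- evolve_codon_pair(bundle$cds[[1]], config$target_ka,
                              config$target_ks,
                              seed = derive_seed(config$seed, "kaks"))
    write_fasta(c(dupA = pair$a, dupB = pair$b), p("kaks_cds.fa"), "DNA")
    write_fasta(c(dupA = translate_cds(pair$a), dupB = translate_cds(pair$b)),
                p("kaks_proteins.fa"), "AA")
  }

  expr <- gen_expression(n_expr_genes, config$n_stages,
                         config$focal_module_size,
                         anti_module_size = max(1L, config$focal_module_size %/% 2L),
                         noise_sd = config$noise_sd,
                         seed = derive_seed(config$seed, "coexpress"))
  write_expression(expr$matrix, p("expression.tsv"))
  write_tsv(expr$truth, p("truth_modules.tsv"))

  tt <- gen_trait_table(n_genotypes, config$trait_r,
                        seed = derive_seed(config$seed, "traits"))
  write_tsv(data.frame(genotype = tt$genotype, ct_target = tt$dct + 20,
                       ct_ref = 20), p("ct.tsv"))
  write_tsv(data.frame(genotype = tt$genotype, FS = tt$trait), p("traits.tsv"))

  paths <- list(
    genome = p("genome.fa"), gff = p("genes.gff3"), cds = p("cds.fa"),
    proteins = p("proteins.fa"), truth_genes = p("truth_genes.tsv"),
    kaks_cds = p("kaks_cds.fa"), kaks_proteins = p("kaks_proteins.fa"),
    expression = p("expression.tsv"), truth_modules = p("truth_modules.tsv"),
    ct = p("ct.tsv"), traits = p("traits.tsv")
  )
  write_manifest(p("manifest_simulate.json"), "simulate", list(),
                 unclass(config), config$seed)
  invisible(paths)
}

#' Scan proteins and report architecture plus properties
#'
#' Produces the family table: id, length, MW, pI, CAMTA/TIG classification,
#' IQ count, domain coordinates and (with a GFF3) intron count.
#'
#' @param proteins_path Protein FASTA path.
#' @param out_path Output TSV path.
#' @param gff_path Optional GFF3 of gene models (for intron counts).
#' @return The report data frame, invisibly.
#' @export
run_scan <- function(proteins_path, out_path, gff_path = NULL) {
  if (!file.exists(proteins_path)) {
    stop("protein FASTA not found: ", proteins_path, call. = FALSE)
  }
  proteins <- read_fasta(proteins_path, "AA")
  introns <- if (!is.null(gff_path)) {
    if (!file.exists(gff_path)) stop("GFF3 not found: ", gff_path, call. = FALSE)
    intron_counts(read_gene_models(gff_path))
  }
  rows <- lapply(names(proteins), function(id) {
    pr <- protein_record(id, proteins[[id]])
    arch <- classify_architecture(scan_all_domains(pr), pr)
    dom <- if (nrow(arch$hits)) {
      paste(sprintf("%s:%d-%d", arch$hits$domain, arch$hits$start,
                    arch$hits$end), collapse = ";")
    } else ""
    mw <- tryCatch(compute_mw(pr), error = function(e) NA_real_)
    data.frame(
      id = id, length = pr$length,
      mw = round(mw, 2), pi = round(compute_pi(pr), 2),
      is_camta = arch$is_camta, tig_type = arch$tig_type,
      iq_count = arch$iq_count,
      n_introns = if (is.null(introns)) NA_integer_ else
        unname(introns[id]) %||% NA_integer_,
      domains = dom, stringsAsFactors = FALSE
    )
  })
  report <- do.call(rbind, rows)
  write_tsv(report, out_path)
  write_manifest(paste0(out_path, ".manifest.json"), "scan",
                 list(proteins = proteins_path, gff = gff_path),
                 list(), NA)
  invisible(report)
}

#' Paralog detection and Ka/Ks report
#'
#' Detects paralog pairs by the coverage/similarity > 70 rule, back-translates
#' each protein alignment onto the CDS, estimates NG86 Ka/Ks, labels
#' selection, dates the duplication (T = Ks / 2 lambda) and, when gene models
#' are given, classifies segmental vs tandem duplication. Ratios are
#' reported to 4 decimals and dates to 2, matching the field's reporting.
#'
#' @param proteins_path,cds_path FASTA paths with matched ids.
#' @param out_path Output TSV.
#' @param gff_path Optional GFF3 for duplication typing.
#' @param lambda_rate Synonymous clock rate per site per year.
#' @param tandem_window Tandem window (bp).
#' @return The report data frame, invisibly.
#' @export
run_kaks <- function(proteins_path, cds_path, out_path, gff_path = NULL,
                     lambda_rate = 1.5e-8, tandem_window = 100000) {
  proteins <- read_fasta(proteins_path, "AA")
  cds <- read_fasta(cds_path, "DNA")
  orphans <- c(setdiff(names(proteins), names(cds)),
               setdiff(names(cds), names(proteins)))
  if (length(orphans)) {
    stop("protein/CDS id mismatch: ", paste(orphans, collapse = ", "),
         call. = FALSE)
  }
  empty <- data.frame(
    id_a = character(), id_b = character(), Ka = numeric(), Ks = numeric(),
    ratio = numeric(), date_mya = numeric(), selection = character(),
    dup_type = character()
  )
  if (length(proteins) < 2L) {
    warning("fewer than 2 sequences; empty report")
    write_tsv(empty, out_path)
    return(invisible(empty))
  }
  models <- if (!is.null(gff_path)) read_gene_models(gff_path)
  pairs <- detect_paralogs(proteins)
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs$id_a[k]; j <- pairs$id_b[k]
    aln <- align_global(protein_record(i, proteins[[i]]),
                        protein_record(j, proteins[[j]]))
    res <- nei_gojobori(backtranslate_alignment(aln, cds[[i]], cds[[j]]))
    dup <- if (!is.null(models)) {
      tryCatch(classify_duplication(c(i, j), models, tandem_window)$dup_type,
               error = function(e) NA_character_)
    } else NA_character_
    data.frame(
      id_a = i, id_b = j, Ka = round(res$Ka, 4), Ks = round(res$Ks, 4),
      ratio = round(res$ratio, 4),
      date_mya = round(date_duplication(res$Ks, lambda_rate), 2),
      selection = res$selection, dup_type = dup, stringsAsFactors = FALSE
    )
  })
  report <- if (length(rows)) do.call(rbind, rows) else empty
  write_tsv(report, out_path)
  write_manifest(paste0(out_path, ".manifest.json"), "kaks",
                 list(proteins = proteins_path, cds = cds_path,
                      gff = gff_path),
                 list(lambda_rate = lambda_rate,
                      tandem_window = tandem_window), NA)
  invisible(report)
}

#' Build and write a focal-gene co-expression network
#'
#' @param expr_path Expression TSV (genes x stages, FPKM).
#' @param focal Focal gene id.
#' @param out_prefix Output prefix (SIF + membership TSV + summaries).
#' @param pos_thr,neg_thr Inclusive correlation thresholds.
#' @param pseudocount Pseudocount for the log2 transform.
#' @return The `coexpression_network`, invisibly.
#' @export
run_coexpress <- function(expr_path, focal, out_prefix, pos_thr = 0.95,
                          neg_thr = -0.95, pseudocount = 1.0) {
  m <- read_expression(expr_path)
  lg <- log2_transform(m, pseudocount)
  r <- focal_correlations(lg, focal)
  net <- build_network(r, pos_thr, neg_thr, focal = focal)
  write_network(net, out_prefix)
  for (set in c("pcoeg", "ncoeg")) {
    if (length(net[[set]])) {
      s <- stage_summary(m, net[[set]])
      write_tsv(data.frame(stat = rownames(s), s, check.names = FALSE),
                paste0(out_prefix, "_", set, "_stage_summary.tsv"))
    }
  }
  write_manifest(paste0(out_prefix, ".manifest.json"), "coexpress",
                 list(expression = expr_path),
                 list(focal = focal, pos_thr = pos_thr, neg_thr = neg_thr,
                      pseudocount = pseudocount), NA)
  invisible(net)
}

#' Promoter motif-enrichment stage
#'
#' Extracts promoters for all genes, tests each listed gene set against a
#' random control sampled from the remaining genes, and writes the per-set
#' enrichment table plus a BED of genomic match coordinates.
#'
#' @param genome_path Genome FASTA.
#' @param gff_path Gene-model GFF3.
#' @param sets A named list of gene-id vectors (the sets to test).
#' @param out_path Output TSV.
#' @param motifs IUPAC motifs.
#' @param promoter_length Promoter length (bp).
#' @param control_n Control-set size (default 700, capped at pool size).
#' @param seed Seed for control sampling.
#' @return The enrichment data frame, invisibly.
#' @export
run_motifs <- function(genome_path, gff_path, sets, out_path,
                       motifs = CAMTA_MOTIFS, promoter_length = 1000L,
                       control_n = 700L, seed = 1L) {
  if (!length(sets) || !length(unlist(sets))) {
    stop("no gene sets supplied to the motif stage", call. = FALSE)
  }
  genome <- read_fasta(genome_path, "DNA")
  models <- read_gene_models(gff_path)
  promoters <- extract_promoters(genome, models, promoter_length)
  all_genes <- names(promoters$entries)
  pool <- setdiff(all_genes, unlist(sets))
  n_ctrl <- min(control_n, length(pool))
  if (n_ctrl < 1L) stop("no genes left for a control set", call. = FALSE)
  control_ids <- sample_control(all_genes, unlist(sets), n_ctrl,
                                seed = derive_seed(seed, "control"))
  control <- promoters$entries[control_ids]
  rows <- lapply(names(sets), function(nm) {
    res <- motif_enrichment(promoters$entries[sets[[nm]]], control,
                            motifs, set_name = nm)
    data.frame(
      set = nm, n = res$n_total, n_with = res$n_with_motif,
      frequency = round(res$frequency, 4),
      control_n = res$control_n_total, control_n_with = res$control_n_with,
      control_frequency = round(res$control_frequency, 4),
      odds_ratio = round(res$odds_ratio, 4), p_value = res$p_value,
      stringsAsFactors = FALSE
    )
  })
  report <- do.call(rbind, rows)
  write_tsv(report, out_path)
  write_bed(promoter_match_bed(genome, models, promoters, motifs),
            paste0(out_path, ".bed"))
  write_manifest(paste0(out_path, ".manifest.json"), "motifs",
                 list(genome = genome_path, gff = gff_path),
                 list(motifs = motifs, promoter_length = promoter_length,
                      control_n = n_ctrl), seed)
  invisible(report)
}

# Map promoter-local match coordinates back to the genome.
promoter_match_bed <- function(genome, models, promoters, motifs) {
  out <- list()
  by_id <- stats::setNames(models, vapply(models, `[[`, character(1), "id"))
  for (id in names(promoters$entries)) {
    hits <- scan_promoter(promoters$entries[[id]], motifs)$positions
    if (!nrow(hits)) next
    gm <- by_id[[id]]
    if (gm$strand == "+") {
      to <- gm$start - 1L
      from <- to - nchar(promoters$entries[[id]]) + 1L
      gstart <- from + hits$start - 1L
      gend <- from + hits$end - 1L
    } else {
      anchor <- gm$end + nchar(promoters$entries[[id]])
      gstart <- anchor - hits$end + 1L
      gend <- anchor - hits$start + 1L
    }
    out[[id]] <- data.frame(chrom = gm$chromosome, start = gstart,
                            end = gend, name = id, stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               name = character())
}

#' Expression-trait correlation stage
#'
#' Reads a Ct table (genotype, ct_target, ct_ref; technical-replicate rows
#' per genotype are averaged on the Ct scale), forms the 1/dCt proxy and
#' correlates it with every trait column.
#'
#' @param ct_path Ct TSV.
#' @param traits_path Trait TSV with a `genotype` column.
#' @param out_path Output TSV.
#' @return The per-trait report, invisibly.
#' @export
run_traits <- function(ct_path, traits_path, out_path) {
  ct <- read.delim(ct_path, stringsAsFactors = FALSE)
  traits <- read.delim(traits_path, stringsAsFactors = FALSE)
  dct <- tapply(ct$ct_target - ct$ct_ref, ct$genotype, mean)
  proxies <- expression_proxy(as.numeric(dct))
  names(proxies) <- names(dct)
  report <- trait_scan(proxies, traits)
  write_tsv(report, out_path)
  write_manifest(paste0(out_path, ".manifest.json"), "traits",
                 list(ct = ct_path, traits = traits_path), list(), NA)
  invisible(report)
}

#' Run the full synthetic end-to-end pipeline
#'
#' simulate -> scan -> kaks -> coexpress -> motifs -> traits, all stage
#' outputs and manifests under `out_dir`.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list of stage reports.
#' @export
run_all <- function(config, out_dir) {
  paths <- run_simulate(config, out_dir)
  scan <- run_scan(paths$proteins, file.path(out_dir, "scan_report.tsv"),
                   gff_path = paths$gff)
  kaks <- run_kaks(paths$kaks_proteins, paths$kaks_cds,
                   file.path(out_dir, "kaks_report.tsv"))
  expr <- read_expression(paths$expression)
  net <- run_coexpress(paths$expression, rownames(expr)[1],
                       file.path(out_dir, "network"))
  truth <- read.delim(paths$truth_genes, stringsAsFactors = FALSE)
  sets <- list(camta = truth$id[truth$planted_camta])
  motifs <- run_motifs(paths$genome, paths$gff, sets,
                       file.path(out_dir, "motif_enrichment.tsv"),
                       control_n = 700L, seed = config$seed)
  traits <- run_traits(paths$ct, paths$traits,
                       file.path(out_dir, "trait_correlations.tsv"))
  invisible(list(scan = scan, kaks = kaks, network = net, motifs = motifs,
                 traits = traits))
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `scan`, `kaks`, `coexpress`, `motifs`, `traits`,
#' `all`. Run via the installed `inst/cli/camtakit` script or
#' `Rscript -e 'camtakit::cli_main()' <subcommand> ...`.
#'
#' @param argv Argument vector (defaults to the command line).
#' @return Integer exit status (0 on success).
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: camtakit <simulate|scan|kaks|coexpress|motifs|traits|all> [options]"
  if (!length(argv)) { message(usage); return(1L) }
  sub <- argv[1]
  rest <- argv[-1]
  opt_list <- list(
    optparse::make_option("--out", type = "character", default = "camtakit_out"),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--proteins", type = "character", default = NULL),
    optparse::make_option("--cds", type = "character", default = NULL),
    optparse::make_option("--genome", type = "character", default = NULL),
    optparse::make_option("--gff", type = "character", default = NULL),
    optparse::make_option("--expression", type = "character", default = NULL),
    optparse::make_option("--focal", type = "character", default = NULL),
    optparse::make_option("--ct", type = "character", default = NULL),
    optparse::make_option("--traits", type = "character", default = NULL),
    optparse::make_option("--sets", type = "character", default = NULL,
                          help = "TSV with columns gene, set"),
    optparse::make_option("--pos-thr", type = "double", default = 0.95),
    optparse::make_option("--neg-thr", type = "double", default = -0.95),
    optparse::make_option("--lambda", type = "double", default = 1.5e-8),
    optparse::make_option("--tandem-window", type = "double", default = 1e5),
    optparse::make_option("--promoter-length", type = "integer", default = 1000L),
    optparse::make_option("--control-n", type = "integer", default = 700L),
    optparse::make_option("--n-genes", type = "integer", default = 12L)
  )
  status <- tryCatch({
    opt <- optparse::parse_args(
      optparse::OptionParser(option_list = opt_list), args = rest
    )
    switch(sub,
      simulate = run_simulate(sim_config(seed = opt$seed,
                                         n_genes = opt$`n-genes`), opt$out),
      scan = run_scan(opt$proteins, file.path_or(opt$out, "scan_report.tsv"),
                      gff_path = opt$gff),
      kaks = run_kaks(opt$proteins, opt$cds,
                      file.path_or(opt$out, "kaks_report.tsv"),
                      gff_path = opt$gff, lambda_rate = opt$lambda,
                      tandem_window = opt$`tandem-window`),
      coexpress = run_coexpress(opt$expression, opt$focal,
                                file.path_or(opt$out, "network"),
                                pos_thr = opt$`pos-thr`,
                                neg_thr = opt$`neg-thr`),
      motifs = {
        sets_df <- read.delim(opt$sets, stringsAsFactors = FALSE)
        run_motifs(opt$genome, opt$gff, split(sets_df$gene, sets_df$set),
                   file.path_or(opt$out, "motif_enrichment.tsv"),
                   promoter_length = opt$`promoter-length`,
                   control_n = opt$`control-n`, seed = opt$seed)
      },
      traits = run_traits(opt$ct, opt$traits,
                          file.path_or(opt$out, "trait_correlations.tsv")),
      all = run_all(sim_config(seed = opt$seed, n_genes = opt$`n-genes`),
                    opt$out),
      stop("unknown subcommand: ", sub, "\n", usage, call. = FALSE)
    )
    0L
  }, error = function(e) {
    message("camtakit error: ", conditionMessage(e))
    1L
  })
  status
}

file.path_or <- function(out, f) {
  if (dir.exists(out) || !grepl("\\.tsv$|\\.json$", out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    file.path(out, f)
  } else {
    out
  }
}
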