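#' Default end-to-end pipeline configuration
#'
#' All analysis thresholds default to the study's printed values: 17-30 nt
#' length window, <150 nt locus gap, hypergeometric alpha 1e-3, two-way
#' ANOVA FDR 0.075, coexpression alpha 0.01, TGTCTC motif within a 1 kb
#' upstream window. Synthetic-data sizes are desk-scale (2 x 200 kb genome,
#' 2e4 reads per library, 1000 genes) so a full run completes in seconds.
#' The two planted GO sets carry genotype/treatment effect correlations of
#' sqrt(0.09) and sqrt(0.387), the coupling strengths the expression stage
#' is expected to recover as R-squared.
#'
#' @param seed Integer master seed; stage seeds are derived from it.
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    genome = list(n_chromosomes = 2L, chrom_length = 200000L,
                  n_features = list(protein_coding_gene = 20L, TE_gene = 8L,
                                    pseudogene = 6L, intergenic_TE = 10L,
                                    MIRNA = 8L, TAS = 3L, tRNA = 4L,
                                    rRNA = 4L, snoRNA = 4L, snRNA = 4L),
                  margin = 1100L),
    motif = list(plant_rate = 0.4, motif = "TGTCTC", window = 1000L),
    smrna = list(depth = 20000L, min_len = 17L, max_len = 30L,
                 gap = 150L, alpha = 1e-3, control = "no_treatment"),
    expression = list(n_genes = 1000L, n_replicates = 3L, noise_sd = 0.25,
                      n_genotype_only = 60L, n_treatment_only = 60L,
                      n_both = 30L, effect_log2 = 2,
                      go_sets = list(
                        list(term = "GO:0009414", size = 150L,
                             rho = sqrt(0.09), effect_sd = 1),
                        list(term = "GO:0048437", size = 150L,
                             rho = sqrt(0.387), effect_sd = 1)),
                      fdr = 0.075, coexpr_alpha = 0.01))
}

#' Validate a pipeline configuration
#' @param config Configuration list.
#' @return The config, invisibly; errors name the offending entry.
#' @export
validate_pipeline_config <- function(config) {
  s <- config$smrna
  stopifnot(s$gap >= 1, s$alpha > 0, s$alpha < 1,
            s$min_len >= 1, s$max_len >= s$min_len, s$depth > 0)
  e <- config$expression
  stopifnot(e$fdr > 0, e$fdr < 1, e$coexpr_alpha > 0, e$coexpr_alpha < 1,
            e$n_replicates >= 2, e$noise_sd > 0)
  m <- config$motif
  stopifnot(m$plant_rate >= 0, m$plant_rate <= 1, m$window >= nchar(m$motif),
            grepl("^[ACGTacgt]+$", m$motif))
  invisible(config)
}

.cfg_go_sets_df <- function(go_sets) {
  if (is.null(go_sets) || length(go_sets) == 0L) return(NULL)
  do.call(rbind, lapply(go_sets, function(g)
    data.frame(term = g$term, size = as.integer(g$size), rho = g$rho,
               effect_sd = g$effect_sd, stringsAsFactors = FALSE)))
}

#' Run the full synthetic-data pipeline
#'
#' Executes simulate -> small-RNA analysis -> factorial expression analysis
#' with structured per-stage logs, and writes a reproducible report bundle.
#' Identical configuration (including seed) yields byte-identical outputs.
#'
#' @param config Configuration list (see [default_pipeline_config()] /
#'   [read_pipeline_config()]).
#' @param outdir Output directory (created if needed); `NULL` skips writing.
#' @return A list of class `run_report`; see Details.
#'
#' @details The report contains `library_summary` (per-library reads in,
#' removed at each filter, retained, distinct signatures and loci — the
#' Table-1-style summary), `signature_summary` (unique signatures and
#' singleton fraction), `composition` (per-library category percentages),
#' `enrichment` (per-family hypergeometric calls), `anova` (per-gene q-values
#' and flags), `venn`, `go_r2` (per planted GO set), `coexpression`,
#' `motif` (hits and per-gene summary plus planted truth recovery), `ddct`,
#' `truth` handles for every stage, and `provenance` (seed and config hash).
#' @export
run_pipeline <- function(config = default_pipeline_config(), outdir = NULL) {
  validate_pipeline_config(config)
  seed <- as.integer(config$seed)
  log <- list()
  stage <- function(name, ...) log[[name]] <<- list(...)

  ## --- synthetic genome with planted promoter motifs
  gspec <- genome_spec(
    n_chromosomes = config$genome$n_chromosomes,
    chrom_length = config$genome$chrom_length,
    n_features = unlist(config$genome$n_features),
    margin = config$genome$margin,
    seed = seed)
  genome <- generate_genome(gspec)
  planted <- plant_promoter_motifs(genome, rate = config$motif$plant_rate,
                                   motif = config$motif$motif,
                                   window = config$motif$window,
                                   seed = seed + 1L)
  genome <- planted$genome
  stage("genome", n_features = length(genome$features),
        n_planted_motifs = nrow(planted$truth))

  ## --- small-RNA libraries and analysis chain
  eff <- smrna_effect_spec(depth = config$smrna$depth, seed = seed + 2L)
  sim <- simulate_smrna_libraries(genome, eff)
  libs <- names(sim$reads)
  reads_in <- vapply(sim$reads, length, integer(1))

  collapsed <- collapse_signatures(sim$reads, min_len = config$smrna$min_len,
                                   max_len = config$smrna$max_len)
  sigs <- stats::setNames(collapsed$signatures$sequence,
                          collapsed$signatures$signature_id)
  mapped <- map_exact(sigs, genome)
  filt <- filter_structural(mapped$hits, genome$features,
                            signature_ids = setdiff(
                              collapsed$signatures$signature_id,
                              c(mapped$unmapped, mapped$invalid)))
  retained_counts <- collapsed$counts[filt$retained, , drop = FALSE]
  dropped_ids <- c(mapped$unmapped, mapped$invalid)
  unmapped_reads <- colSums(collapsed$counts[dropped_ids, , drop = FALSE])
  structural_reads <- colSums(collapsed$counts[filt$removed, , drop = FALSE])
  retained_reads <- colSums(retained_counts)
  stage("filters",
        removed_by_length = collapsed$removed_by_length,
        unmapped_signatures = length(mapped$unmapped),
        invalid_signatures = length(mapped$invalid),
        structural_signatures = length(filt$removed),
        retained_signatures = length(filt$retained))

  classes <- classify_signatures(filt$hits, genome$features)
  comp <- tabulate_composition(classes, retained_counts)
  loci <- cluster_loci(filt$hits, gap = config$smrna$gap)
  lib_loci <- count_library_loci(filt$hits, retained_counts,
                                 gap = config$smrna$gap)
  n_seq_lib <- colSums(retained_counts > 0L)

  fams <- assign_families(filt$hits, genome$features, classes)
  fc <- family_counts(fams, retained_counts)
  mirna_totals <- comp$counts["miRNA", ]
  abundance <- normalize_by_mirna(fc$counts, mirna_totals,
                                  control = config$smrna$control)
  enrichment <- enrich_families(fc$counts, fc$family_class, mirna_totals,
                                control = config$smrna$control,
                                alpha = config$smrna$alpha)
  library_summary <- data.frame(
    library = libs,
    reads_in = reads_in,
    removed_by_length = collapsed$removed_by_length[libs],
    unmapped_reads = unmapped_reads[libs],
    structural_reads = structural_reads[libs],
    retained_reads = retained_reads[libs],
    n_sequences = as.integer(n_seq_lib[libs]),
    n_loci = as.integer(lib_loci[libs]),
    stringsAsFactors = FALSE, row.names = NULL)
  stopifnot(all(library_summary$reads_in ==
                  library_summary$removed_by_length +
                  library_summary$unmapped_reads +
                  library_summary$structural_reads +
                  library_summary$retained_reads))
  stage("smrna", n_loci_overall = length(loci),
        n_families = nrow(fc$counts),
        n_significant = sum(enrichment$significant))

  ## --- factorial expression analysis
  ecfg <- config$expression
  go_df <- .cfg_go_sets_df(ecfg$go_sets)
  n_go <- if (is.null(go_df)) 0L else sum(go_df$size)
  g_eff <- t_eff <- rep(0, ecfg$n_genes)
  at <- n_go + 1L
  take <- function(n) { ix <- seq.int(at, at + n - 1L); at <<- at + n; ix }
  ix_g <- take(ecfg$n_genotype_only)
  ix_t <- take(ecfg$n_treatment_only)
  ix_b <- take(ecfg$n_both)
  g_eff[c(ix_g, ix_b)] <- ecfg$effect_log2
  t_eff[c(ix_t, ix_b)] <- ecfg$effect_log2
  espec <- expression_effect_spec(
    n_genes = ecfg$n_genes, n_replicates = ecfg$n_replicates,
    genotype_effect = g_eff, treatment_effect = t_eff,
    noise_sd = ecfg$noise_sd, go_sets = go_df, seed = seed + 3L)
  fm <- simulate_expression_matrix(espec)
  # designate two planted treatment-responsive genes as the anchor
  # transcription factors for the coexpression screen
  anchors <- c("ARF3", "ARF4")
  rn <- rownames(fm$exprs)
  rn[ix_t[1:2]] <- anchors
  rownames(fm$exprs) <- rn
  fm$truth$gene_id <- rn

  fm_norm <- percentile75_normalize(fm)
  records <- anova_fdr(two_way_anova(fm_norm), fdr = ecfg$fdr)
  venn <- venn_partition(records, threshold = ecfg$fdr)
  ratios <- genotype_treatment_ratios(fm_norm)
  go_r2 <- if (!is.null(go_df)) {
    do.call(rbind, lapply(seq_len(nrow(go_df)), function(j) {
      members <- fm$go_memberships$gene_id[
        fm$go_memberships$term == go_df$term[j]]
      r2 <- go_scatter_r2(ratios$pairs, members)
      data.frame(term = go_df$term[j], planted_rho = go_df$rho[j],
                 planted_r_squared = go_df$rho[j]^2,
                 observed_r_squared = r2$r_squared, sign = r2$sign,
                 n = r2$n, stringsAsFactors = FALSE)
    }))
  } else NULL
  coex <- coexpression_screen(fm_norm$exprs, anchors = anchors,
                              alpha = ecfg$coexpr_alpha)
  stage("expression", n_flagged = venn$total,
        n_coexpressed = length(coex$genes))

  ## --- promoter motif scan and qPCR readback
  scan <- scan_promoter_motif(genome, motif = config$motif$motif,
                              window = config$motif$window)
  planted_found <- if (nrow(planted$truth) > 0L)
    mean(paste(planted$truth$gene_id, planted$truth$offset) %in%
           paste(scan$hits$gene_id, scan$hits$offset)) else NA_real_
  ct_samples <- c("WT_NS", "WT_D", "rdr6_NS", "rdr6_D")
  ct <- simulate_ct_table(
    ct_samples,
    relative_level = stats::setNames(c(1, 0.4, 1.1, 0.9), ct_samples),
    calibrator = "WT_NS", seed = seed + 4L)
  ddct <- delta_delta_ct(ct, calibrator = "WT_NS")
  stage("motif", n_genes_with_hit = sum(scan$gene_summary$has_motif),
        planted_recovered_fraction = planted_found)

  report <- structure(list(
    library_summary = library_summary,
    signature_summary = collapsed$summary,
    composition = comp,
    loci = loci,
    abundance = abundance,
    enrichment = enrichment,
    anova = records,
    venn = venn,
    ratios = ratios$pairs,
    go_r2 = go_r2,
    coexpression = coex,
    motif = list(hits = scan$hits, gene_summary = scan$gene_summary,
                 planted_recovered_fraction = planted_found),
    ddct = ddct,
    truth = list(genome = genome, motif = planted$truth,
                 smrna = sim$truth, expression = fm$truth,
                 go_memberships = fm$go_memberships),
    log = log,
    provenance = list(seed = seed, config = config)),
    class = "run_report")
  if (!is.null(outdir)) write_run_report(report, outdir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report (seed", x$provenance$seed, ")\n\n")
  cat("Per-library summary (sequences after filters, loci):\n")
  print(x$library_summary[, c("library", "n_sequences", "n_loci")],
        row.names = FALSE)
  ss <- x$signature_summary
  cat(sprintf("\nUnique signatures: %d; singletons: %d (%.1f%%)\n",
              ss$n_unique, ss$n_singleton, 100 * ss$singleton_fraction))
  cat(sprintf("Significant enrichment calls: %d\n",
              sum(x$enrichment$significant)))
  cat(sprintf("DE genes (Venn): genotype-only %d, treatment-only %d, both %d\n",
              x$venn$genotype_only, x$venn$treatment_only, x$venn$both))
  if (!is.null(x$go_r2)) {
    cat("GO-set R-squared (planted -> observed):\n")
    for (j in seq_len(nrow(x$go_r2)))
      cat(sprintf("  %s: %.3f -> %.3f\n", x$go_r2$term[j],
                  x$go_r2$planted_r_squared[j], x$go_r2$observed_r_squared[j]))
  }
  cat(sprintf("Coexpressed with both anchors: %d genes\n",
              length(x$coexpression$genes)))
  cat(sprintf("Genes with promoter motif: %d\n",
              sum(x$motif$gene_summary$has_motif)))
  invisible(x)
}

#' Write a report bundle (TSVs + human-readable summary)
#'
#' Output is a pure function of the report: identical config + seed produce
#' byte-identical files.
#'
#' @param report A `run_report`.
#' @param outdir Output directory.
#' @export
write_run_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_tsv_table(report$library_summary, p("library_summary.tsv"))
  comp <- data.frame(category = rownames(report$composition$percentages),
                     report$composition$percentages, check.names = FALSE)
  write_tsv_table(comp, p("composition_percent.tsv"))
  write_tsv_table(report$abundance, p("family_abundance.tsv"))
  write_tsv_table(report$enrichment, p("enrichment.tsv"))
  write_loci_bed(report$loci, p("loci.bed"))
  write_tsv_table(report$anova, p("anova.tsv"))
  write_tsv_table(report$ratios, p("ratio_pairs.tsv"))
  if (!is.null(report$go_r2)) write_tsv_table(report$go_r2, p("go_r2.tsv"))
  write_tsv_table(report$motif$hits, p("motif_hits.tsv"))
  write_tsv_table(report$ddct, p("relative_expression.tsv"))
  cfg_path <- p("config.yaml")
  write_pipeline_config(report$provenance$config, cfg_path)
  md5 <- unname(tools::md5sum(cfg_path))
  con <- file(p("summary.txt"), open = "wt")
  sink(con)
  on.exit({ sink(); close(con) }, add = TRUE)
  print(report)
  cat(sprintf("\nconfig md5: %s\n", md5))
  invisible(outdir)
}
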