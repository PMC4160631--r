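# Hand-built micro-genomes and desk-scale configurations shared across tests.

# single-chromosome genome from an explicit sequence and feature table
tiny_genome <- function(sequence,
                        features = data.frame(start = integer(0),
                                              end = integer(0),
                                              strand = character(0),
                                              type = character(0),
                                              ID = character(0))) {
  seqs <- Biostrings::DNAStringSet(sequence)
  names(seqs) <- "chr1"
  if (nrow(features) > 0L) {
    gr <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(features$start, features$end),
                                 strand = features$strand)
    S4Vectors::mcols(gr)$ID <- features$ID
    S4Vectors::mcols(gr)$type <- features$type
    S4Vectors::mcols(gr)$mature_start <-
      if ("mature_start" %in% colnames(features)) features$mature_start
      else rep(NA_integer_, nrow(features))
    S4Vectors::mcols(gr)$phase_start <-
      if ("phase_start" %in% colnames(features)) features$phase_start
      else rep(NA_integer_, nrow(features))
  } else {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$ID <- character(0)
    S4Vectors::mcols(gr)$type <- character(0)
    S4Vectors::mcols(gr)$mature_start <- integer(0)
    S4Vectors::mcols(gr)$phase_start <- integer(0)
  }
  GenomeInfoDb::seqlevels(gr) <- "chr1"
  GenomeInfoDb::seqlengths(gr) <- c(chr1 = nchar(sequence))
  structure(list(seqs = seqs, features = gr), class = "annotated_genome")
}

# hits GRanges from coordinate triplets
make_hits <- function(chrom, start, end, strand = "+",
                      signature_id = sprintf("S%06d", seq_along(start))) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               strand = strand)
  S4Vectors::mcols(gr)$signature_id <- signature_id
  gr
}

# plus-strand gene placed right after an explicit promoter sequence, so the
# scanned upstream window is exactly that promoter
promoter_genome <- function(promoter) {
  body <- strrep("A", 60)
  tiny_genome(paste0(promoter, body),
              data.frame(start = nchar(promoter) + 1L,
                         end = nchar(promoter) + 60L, strand = "+",
                         type = "protein_coding_gene", ID = "PC0001"))
}

# desk-scale pipeline configuration for fast end-to-end tests
small_pipeline_config <- function(seed = 1L) {
  cfg <- default_pipeline_config(seed = seed)
  cfg$genome$chrom_length <- 60000L
  cfg$genome$n_features <- list(protein_coding_gene = 6L, TE_gene = 3L,
                                pseudogene = 2L, intergenic_TE = 3L,
                                MIRNA = 5L, TAS = 2L, tRNA = 2L, rRNA = 2L,
                                snoRNA = 1L, snRNA = 1L)
  cfg$smrna$depth <- 3000L
  cfg$expression$n_genes <- 300L
  cfg$expression$n_genotype_only <- 20L
  cfg$expression$n_treatment_only <- 20L
  cfg$expression$n_both <- 10L
  cfg$expression$go_sets <- list(
    list(term = "GO:0009414", size = 50L, rho = sqrt(0.09), effect_sd = 1),
    list(term = "GO:0048437", size = 50L, rho = sqrt(0.387), effect_sd = 1))
  cfg
}

# genome sized for enrichment simulations: many miRNA/TAS families
enrichment_genome <- function(seed = 1L, n_mirna = 30L, n_tas = 10L) {
  generate_genome(genome_spec(
    n_chromosomes = 2L, chrom_length = 400000L,
    n_features = c(protein_coding_gene = 10L, TE_gene = 4L, pseudogene = 2L,
                   intergenic_TE = 4L, MIRNA = n_mirna, TAS = n_tas,
                   tRNA = 2L, rRNA = 2L, snoRNA = 1L, snRNA = 1L),
    margin = 1100L, seed = seed))
}

# run the smRNA chain (collapse/map/filter/classify/families/enrich) on
# simulated libraries; returns the pieces tests need
run_smrna_chain <- function(genome, sim, alpha = 1e-3,
                            control = "no_treatment") {
  collapsed <- collapse_signatures(sim$reads)
  sigs <- stats::setNames(collapsed$signatures$sequence,
                          collapsed$signatures$signature_id)
  mapped <- map_exact(sigs, genome)
  filt <- filter_structural(mapped$hits, genome$features)
  counts <- collapsed$counts[filt$retained, , drop = FALSE]
  classes <- classify_signatures(filt$hits, genome$features)
  comp <- tabulate_composition(classes, counts)
  fams <- assign_families(filt$hits, genome$features, classes)
  fc <- family_counts(fams, counts)
  enr <- enrich_families(fc$counts, fc$family_class,
                         comp$counts["miRNA", ], control = control,
                         alpha = alpha)
  list(collapsed = collapsed, mapped = mapped, filt = filt, counts = counts,
       classes = classes, comp = comp, fams = fams, fc = fc, enr = enr)
}
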