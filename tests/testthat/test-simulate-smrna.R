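test_that("forced compositions are honored by the read simulator", {
  g <- generate_genome(genome_spec(
    n_chromosomes = 1L, chrom_length = 60000L,
    n_features = c(MIRNA = 4L, protein_coding_gene = 3L), margin = 600L,
    seed = 21L))
  # degradation 0, background 0, only MIRNA expressed: every read lies
  # inside a MIRNA locus
  eff <- smrna_effect_spec(
    libraries = c("drought_1_5h", "no_treatment"), depth = 500L,
    class_weights = c(MIRNA = 1),
    fold_changes = NULL, degradation_fraction = 0, background_fraction = 0,
    seed = 3L)
  sim <- simulate_smrna_libraries(g, eff)
  mir <- g$features[S4Vectors::mcols(g$features)$type == "MIRNA"]
  for (lib in names(sim$read_origins)) {
    tab <- sim$read_origins[[lib]]
    expect_equal(nrow(tab), 500L)  # counts sum to the requested depth
    gr <- GenomicRanges::GRanges(tab$chrom, IRanges::IRanges(tab$start, tab$end))
    expect_true(all(IRanges::overlapsAny(gr, mir)))
  }
})

test_that("a zero TAS fold-change silences TAS reads only where applied", {
  g <- generate_genome(genome_spec(
    n_chromosomes = 1L, chrom_length = 80000L,
    n_features = c(MIRNA = 4L, TAS = 3L, protein_coding_gene = 3L),
    margin = 600L, seed = 22L))
  eff <- smrna_effect_spec(
    libraries = c("drought_1_5h", "no_treatment"), depth = 2000L,
    class_weights = c(MIRNA = 1, TAS = 1),
    fold_changes = data.frame(library = "drought_1_5h", target = "class:TAS",
                              multiplier = 0),
    degradation_fraction = 0, background_fraction = 0, seed = 4L)
  sim <- simulate_smrna_libraries(g, eff)
  tas_ids <- S4Vectors::mcols(g$features)$ID[
    S4Vectors::mcols(g$features)$type == "TAS"]
  expect_equal(sum(sim$truth$counts[tas_ids, "drought_1_5h"]), 0L)
  expect_gt(sum(sim$truth$counts[tas_ids, "no_treatment"]), 0L)
})

test_that("TAS emissions are 21 nt reads cut in phase from the phase start", {
  g <- generate_genome(genome_spec(n_chromosomes = 1L, chrom_length = 60000L,
                                   n_features = c(TAS = 2L), margin = 600L,
                                   seed = 23L))
  eff <- smrna_effect_spec(libraries = "no_treatment", depth = 400L,
                           class_weights = c(TAS = 1), fold_changes = NULL,
                           degradation_fraction = 0, background_fraction = 0,
                           seed = 5L)
  sim <- simulate_smrna_libraries(g, eff)
  tab <- sim$read_origins$no_treatment
  expect_true(all(tab$end - tab$start + 1L == 21L))
  feats <- g$features
  ps <- stats::setNames(S4Vectors::mcols(feats)$phase_start,
                        S4Vectors::mcols(feats)$ID)
  expect_true(all((tab$start - ps[tab$origin]) %% 21L == 0L))
})

test_that("a planted 0.25 TAS fold-change is recovered within sampling error", {
  g <- generate_genome(genome_spec(seed = 24L))
  eff <- smrna_effect_spec(
    libraries = c("drought_1_5h", "no_treatment"), depth = 10000L,
    fold_changes = data.frame(library = "drought_1_5h", target = "class:TAS",
                              multiplier = 0.25),
    degradation_fraction = c(drought_1_5h = 0.1, no_treatment = 0.1),
    seed = 6L)
  sim <- simulate_smrna_libraries(g, eff)
  tas_ids <- S4Vectors::mcols(g$features)$ID[
    S4Vectors::mcols(g$features)$type == "TAS"]
  n_d <- sum(sim$truth$counts[tas_ids, "drought_1_5h"])
  n_c <- sum(sim$truth$counts[tas_ids, "no_treatment"])
  ratio <- n_d / n_c
  sd_ratio <- ratio * sqrt(1 / n_d + 1 / n_c)
  expect_lt(abs(ratio - 0.25), 3 * sd_ratio)
})

test_that("invalid effect specifications fail explicitly", {
  expect_error(smrna_effect_spec(depth = 0L), "depth")
  g <- generate_genome(genome_spec(n_chromosomes = 1L, chrom_length = 60000L,
                                   n_features = c(MIRNA = 2L), margin = 600L,
                                   seed = 25L))
  eff <- smrna_effect_spec(
    libraries = "no_treatment", depth = 100L,
    class_weights = c(MIRNA = 1),
    fold_changes = data.frame(library = "no_treatment",
                              target = "locus:NOPE01", multiplier = 2),
    degradation_fraction = 0, background_fraction = 0, seed = 1L)
  expect_error(simulate_smrna_libraries(g, eff), "NOPE01")
})

test_that("library read counts always sum to the requested depth", {
  g <- generate_genome(genome_spec(seed = 26L))
  eff <- smrna_effect_spec(depth = 1500L, seed = 7L)
  sim <- simulate_smrna_libraries(g, eff)
  expect_equal(unname(vapply(sim$reads, length, integer(1))),
               rep(1500L, 7L))
  expect_equal(unname(colSums(sim$truth$counts)), rep(1500L, 7L))
  # determinism: same genome and spec give identical libraries
  sim2 <- simulate_smrna_libraries(g, eff)
  expect_identical(sim$reads, sim2$reads)
})
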