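cls_fixture <- function() {
  feats <- data.frame(
    start = c(100L, 400L, 700L, 1000L, 1300L, 1600L),
    end = c(200L, 500L, 800L, 1100L, 1400L, 1700L),
    strand = c("+", "+", "+", "+", "+", "+"),
    type = c("MIRNA", "TAS", "protein_coding_gene", "TE_gene", "pseudogene",
             "intergenic_TE"),
    ID = c("MIR0001", "TAS0001", "PC0001", "TE0001", "PS0001", "ITE0001"))
  tiny_genome(strrep("ACGT", 500), feats)
}

test_that("classification applies the category precedence over all hits", {
  g <- cls_fixture()
  hits <- make_hits(
    "chr1",
    start = c(150L, 750L,   750L,  720L,  1050L, 1350L, 1650L, 1900L),
    end   = c(170L, 770L,   770L,  740L,  1070L, 1370L, 1670L, 1920L),
    strand = c("+",  "+",    "+",   "-",   "+",   "+",   "+",   "+"),
    signature_id = c("Smir", "Smir", "Ssense", "Santi", "Ste", "Sps",
                     "Site", "Sint"))
  cl <- classify_signatures(hits, g$features)
  got <- stats::setNames(cl$category, cl$signature_id)
  # hit inside a MIRNA locus and also inside a gene: miRNA wins
  expect_equal(unname(got["Smir"]), "miRNA")
  expect_equal(unname(got["Ssense"]), "protein_coding_sense")
  # minus-strand hit over a plus-strand gene only: antisense
  expect_equal(unname(got["Santi"]), "protein_coding_antisense")
  expect_equal(unname(got["Ste"]), "TE_gene")
  expect_equal(unname(got["Sps"]), "pseudogene")
  expect_equal(unname(got["Site"]), "intergenic_TE")
  # no feature overlap: fallback category
  expect_equal(unname(got["Sint"]), "other_intergenic")
})

test_that("ta-siRNA precedence sits between miRNA and protein-coding", {
  g <- cls_fixture()
  hits <- make_hits("chr1", c(450L, 750L), c(470L, 770L),
                    signature_id = c("S1", "S1"))
  cl <- classify_signatures(hits, g$features)
  expect_equal(cl$category, "ta_siRNA")
})

test_that("composition percentages are read-weighted and sum to 100", {
  classes <- data.frame(signature_id = c("S1", "S2"),
                        category = c("miRNA", "protein_coding_sense"))
  counts <- matrix(c(50L, 50L), ncol = 1,
                   dimnames = list(c("S1", "S2"), "lib1"))
  comp <- tabulate_composition(classes, counts)
  expect_equal(comp$percentages["miRNA", "lib1"], 50)
  expect_equal(comp$percentages["protein_coding_sense", "lib1"], 50)
  expect_equal(sum(comp$percentages[, "lib1"]), 100)

  # single-category library
  counts2 <- matrix(c(7L, 0L), ncol = 1,
                    dimnames = list(c("S1", "S2"), "lib1"))
  comp2 <- tabulate_composition(classes, counts2)
  expect_equal(comp2$percentages["miRNA", "lib1"], 100)

  # empty library flagged
  counts3 <- matrix(c(0L, 0L), ncol = 1,
                    dimnames = list(c("S1", "S2"), "lib1"))
  expect_equal(tabulate_composition(classes, counts3)$empty_libraries, "lib1")
})

test_that("higher degradation raises the sense-strand share of a library", {
  g <- generate_genome(genome_spec(seed = 51L))
  eff <- smrna_effect_spec(
    libraries = c("drought_1_5h", "no_treatment"), depth = 8000L,
    fold_changes = NULL,
    degradation_fraction = c(drought_1_5h = 0.3, no_treatment = 0.1),
    seed = 8L)
  sim <- simulate_smrna_libraries(g, eff)
  chain <- run_smrna_chain(g, sim)
  pct <- chain$comp$percentages
  expect_gt(pct["protein_coding_sense", "drought_1_5h"],
            pct["protein_coding_sense", "no_treatment"])
})

test_that("family assignment aggregates counts per MIRNA/TAS locus", {
  g <- cls_fixture()
  hits <- make_hits("chr1", c(150L, 160L, 450L), c(170L, 180L, 470L),
                    signature_id = c("S1", "S2", "S3"))
  classes <- classify_signatures(hits, g$features)
  fams <- assign_families(hits, g$features, classes)
  expect_setequal(fams$family[fams$family_class == "MIRNA"], "MIR0001")
  expect_setequal(fams$family[fams$family_class == "TAS"], "TAS0001")
  counts <- matrix(c(3L, 2L, 4L), ncol = 1,
                   dimnames = list(c("S1", "S2", "S3"), "lib1"))
  fc <- family_counts(fams, counts)
  expect_equal(fc$counts["MIR0001", "lib1"], 5L)
  expect_equal(fc$counts["TAS0001", "lib1"], 4L)
})
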