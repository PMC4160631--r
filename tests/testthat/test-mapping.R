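test_that("collapsing reads conserves counts and finds singletons", {
  r17a <- strrep("A", 17)
  r17c <- strrep("C", 17)
  col <- collapse_signatures(list(lib1 = c(r17a, r17a, r17c)))
  expect_equal(nrow(col$signatures), 2L)
  expect_equal(sort(col$signatures$total), c(1L, 2L))
  expect_equal(sum(col$counts), 3L)
  expect_equal(col$summary$singleton_fraction, 0.5)
  # most abundant signature gets the first id
  expect_equal(col$signatures$sequence[1], r17a)

  # empty input: empty output, undefined fraction reported as NA
  e <- collapse_signatures(list(lib1 = character(0)))
  expect_equal(e$summary$n_unique, 0L)
  expect_true(is.na(e$summary$singleton_fraction))

  # ten distinct reads once each: all singletons
  reads <- vapply(1:10, function(i) random_dna(20), character(1))
  u <- collapse_signatures(list(lib1 = unique(reads)))
  expect_equal(u$summary$singleton_fraction, 1)

  # the 17-30 nt window is applied before collapsing
  f <- collapse_signatures(list(lib1 = c(strrep("A", 16), strrep("A", 31),
                                         r17a)))
  expect_equal(nrow(f$signatures), 1L)
  expect_equal(unname(f$removed_by_length["lib1"]), 2L)
})

test_that("exact mapping reports every occurrence on both strands", {
  g <- tiny_genome("AAAACCCGGGTTTT")
  res <- map_exact(c(S1 = "CCCGG"), g)
  df <- data.frame(start = GenomicRanges::start(res$hits),
                   strand = as.character(BiocGenerics::strand(res$hits)))
  # 1-based starts: plus hit at 5, reverse-complement (CCGGG) hit at 6
  expect_equal(df[order(df$start), "start"], c(5L, 6L))
  expect_setequal(df$strand, c("+", "-"))

  # absent read: unmapped flag, empty hit list
  res2 <- map_exact(c(S1 = "ACGTACGTACGTACGTA"), tiny_genome(strrep("A", 100)))
  expect_equal(res2$unmapped, "S1")
  expect_length(res2$hits, 0L)

  # palindromic read: plus and minus hits at the same start
  res3 <- map_exact(c(S1 = "ACGT"), tiny_genome("TTACGTTT"))
  expect_equal(GenomicRanges::start(res3$hits), c(3L, 3L))
  expect_setequal(as.character(BiocGenerics::strand(res3$hits)), c("+", "-"))

  # ambiguous bases: flagged invalid, not silently dropped
  res4 <- map_exact(c(S1 = "ACGNACGT"), g)
  expect_equal(res4$invalid, "S1")
})

test_that("exact mapping equals the naive both-strand scan", {
  set.seed(31)
  seqs <- Biostrings::DNAStringSet(c(chr1 = random_dna(3000),
                                     chr2 = random_dna(2000)))
  g <- structure(list(seqs = seqs, features = GenomicRanges::GRanges()),
                 class = "annotated_genome")
  # reads drawn from the genome (mostly mappable) plus random ones
  reads <- c(
    vapply(1:15, function(i) {
      ch <- sample(1:2, 1)
      st <- sample(1900, 1)
      substr(as.character(seqs[[ch]]), st, st + sample(17:30, 1) - 1L)
    }, character(1)),
    vapply(1:5, function(i) random_dna(20), character(1)))
  names(reads) <- sprintf("S%06d", seq_along(reads))
  res <- map_exact(reads, g)
  hit_df <- data.frame(
    id = S4Vectors::mcols(res$hits)$signature_id,
    chrom = as.character(GenomeInfoDb::seqnames(res$hits)),
    start = GenomicRanges::start(res$hits),
    strand = as.character(BiocGenerics::strand(res$hits)),
    stringsAsFactors = FALSE)
  for (id in names(reads)) {
    oracle <- naive_map(reads[[id]], seqs)
    got <- hit_df[hit_df$id == id, c("chrom", "start", "strand")]
    got <- got[order(got$chrom, got$start, got$strand), ]
    rownames(got) <- rownames(oracle) <- NULL
    expect_equal(got, oracle, info = id)
  }
})

test_that("structural-RNA filtering removes any signature with a structural hit", {
  feats <- data.frame(start = c(10L, 200L), end = c(100L, 300L),
                      strand = c("+", "+"),
                      type = c("rRNA", "protein_coding_gene"),
                      ID = c("RRNA0001", "PC0001"))
  g <- tiny_genome(strrep("ACGT", 100), feats)
  hits <- make_hits("chr1", c(20L, 250L, 220L), c(40L, 270L, 240L),
                    signature_id = c("S1", "S2", "S1"))
  res <- filter_structural(hits, g$features)
  # S1 has one rRNA hit and one gene hit: any structural hit disqualifies
  expect_equal(res$removed, "S1")
  expect_equal(res$retained, "S2")
  expect_true(all(S4Vectors::mcols(res$hits)$signature_id == "S2"))

  # no structural features: output equals input
  g2 <- tiny_genome(strrep("ACGT", 100), feats[2, , drop = FALSE])
  res2 <- filter_structural(hits, g2$features)
  expect_length(res2$removed, 0L)
  expect_identical(res2$hits, hits)

  # unmapped signature encountered: explicit failure
  expect_error(filter_structural(hits, g$features,
                                 signature_ids = c("S1", "S2", "S9")),
               "unmapped")
})
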