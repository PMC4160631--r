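samples_2x2 <- function(r) data.frame(
  sample = sprintf("s%d", seq_len(4 * r)),
  genotype = rep(c("WT", "rdr6"), each = 2 * r),
  treatment = rep(rep(c("nonstressed", "drought"), each = r), 2),
  replicate = rep(seq_len(r), 4), stringsAsFactors = FALSE)

test_that("75th-percentile normalization uses linear interpolation", {
  m <- matrix(c(1, 2, 3, 4), ncol = 1, dimnames = list(letters[1:4], "s1"))
  out <- percentile75_normalize(m)
  expect_equal(out[, 1], c(1, 2, 3, 4) / 3.25, ignore_attr = TRUE)
  expect_equal(unname(stats::quantile(out[, 1], 0.75, type = 7)), 1)
  # idempotent on already-normalized input
  expect_equal(percentile75_normalize(out), out)
  # scalar-multiple samples become identical
  m2 <- cbind(s1 = c(1, 2, 3, 4), s2 = c(10, 20, 30, 40))
  rownames(m2) <- letters[1:4]
  out2 <- percentile75_normalize(m2)
  expect_equal(out2[, "s1"], out2[, "s2"])
  # nonpositive intensity names the offending cell
  m3 <- m; m3[2, 1] <- 0
  expect_error(percentile75_normalize(m3), "b.*s1")
})

test_that("two-way ANOVA reproduces the textbook sums-of-squares example", {
  s <- samples_2x2(2)
  # WT cells {1,2}/{1,2}, rdr6 cells {3,4}/{3,4} on the log2 scale
  y <- rbind(g1 = c(1, 2, 1, 2, 3, 4, 3, 4))
  colnames(y) <- s$sample
  res <- two_way_anova(y, s, log2_transform = FALSE)
  expect_equal(res$F_genotype, 16)
  expect_equal(res$p_genotype, stats::pf(16, 1, 4, lower.tail = FALSE))
  expect_equal(res$p_genotype, 0.0161, tolerance = 1e-2)
  expect_equal(res$F_treatment, 0)
  expect_equal(res$p_treatment, 1)
  expect_false(res$degenerate)
})

test_that("two-way ANOVA matches stats::aov on random balanced data", {
  set.seed(71)
  s <- samples_2x2(3)
  y <- matrix(stats::rnorm(20 * 12, mean = 8), nrow = 20,
              dimnames = list(sprintf("g%02d", 1:20), s$sample))
  res <- two_way_anova(y, s, log2_transform = FALSE)
  for (i in seq_len(nrow(y))) {
    fit <- stats::aov(y[i, ] ~ factor(s$genotype) * factor(s$treatment))
    p <- summary(fit)[[1]][["Pr(>F)"]]
    expect_equal(res$p_genotype[i], p[1], tolerance = 1e-10)
    expect_equal(res$p_treatment[i], p[2], tolerance = 1e-10)
    expect_equal(res$p_interaction[i], p[3], tolerance = 1e-10)
  }
})

test_that("ANOVA is invariant to replicate order and flags zero variance", {
  set.seed(72)
  s <- samples_2x2(3)
  y <- matrix(stats::rnorm(5 * 12), nrow = 5)
  colnames(y) <- s$sample
  res <- two_way_anova(y, s, log2_transform = FALSE)
  # permute replicates within each design cell
  perm <- unlist(lapply(split(seq_len(12), interaction(s$genotype, s$treatment)),
                        sample))
  res_p <- two_way_anova(y[, perm], s[perm, ], log2_transform = FALSE)
  expect_equal(res$p_genotype, res_p$p_genotype)
  expect_equal(res$p_treatment, res_p$p_treatment)
  # all values equal: degenerate, no NaN propagation
  flat <- matrix(5, nrow = 1, ncol = 12, dimnames = list("g1", s$sample))
  resf <- two_way_anova(flat, s, log2_transform = FALSE)
  expect_true(resf$degenerate)
  expect_true(is.na(resf$p_genotype))
})

test_that("BH q-values match the step-up hand calculation", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.5), 0.5)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
})

test_that("Venn partition counts genes by their two main-effect flags", {
  rec <- data.frame(q_genotype = c(0.05, 0.5, 0.05, 0.5),
                    q_treatment = c(0.5, 0.05, 0.05, 0.5))
  v <- venn_partition(rec, threshold = 0.075)
  expect_equal(v, list(genotype_only = 1L, treatment_only = 1L, both = 1L,
                       total = 3L))
  v0 <- venn_partition(data.frame(q_genotype = 0.9, q_treatment = 0.9))
  expect_equal(v0$total, 0L)
})

test_that("ratio pairs follow the cell-mean definition and its symmetries", {
  s <- samples_2x2(2)
  cells <- function(wt_ns, wt_d, r_ns, r_d)
    matrix(rep(c(wt_ns, wt_d, r_ns, r_d), each = 2), nrow = 1,
           dimnames = list("g1", s$sample))
  # all cell means equal -> (0, 0)
  r0 <- genotype_treatment_ratios(cells(10, 10, 10, 10), s)
  expect_equal(unlist(r0$pairs[, c("x", "y")]), c(x = 0, y = 0))
  # rdr6 doubled, no treatment effect -> x = 1, y = 0
  r1 <- genotype_treatment_ratios(cells(10, 10, 20, 20), s)
  expect_equal(r1$pairs$x, 1)
  expect_equal(r1$pairs$y, 0)
  # swapping genotype labels negates x and leaves y unchanged
  set.seed(73)
  y <- matrix(2^stats::rnorm(8, 8), nrow = 1, dimnames = list("g1", s$sample))
  fwd <- genotype_treatment_ratios(y, s)
  s_sw <- s; s_sw$genotype <- ifelse(s$genotype == "WT", "rdr6", "WT")
  swp <- genotype_treatment_ratios(y, s_sw)
  expect_equal(swp$pairs$x, -fwd$pairs$x)
  expect_equal(swp$pairs$y, fwd$pairs$y)
  # zero cell mean excludes the gene
  yz <- y; yz[1, 1:2] <- 0
  expect_error(percentile75_normalize(yz))  # guarded upstream
  rz <- genotype_treatment_ratios(yz, s)
  expect_equal(rz$excluded, "g1")
})

test_that("GO-set R-squared is the squared Pearson correlation of the pair", {
  p <- data.frame(gene_id = c("a", "b", "c"), x = c(1, 2, 3), y = c(2, 4, 6))
  expect_equal(go_scatter_r2(p, p$gene_id)$r_squared, 1)
  p2 <- data.frame(gene_id = c("a", "b", "c"), x = c(0, 1, 2), y = c(0, 1, 0))
  expect_equal(go_scatter_r2(p2, p2$gene_id)$r_squared, 0)
  # permutation invariance
  expect_equal(go_scatter_r2(p2[c(3, 1, 2), ], p2$gene_id)$r_squared, 0)
  # degenerate cases reported, not propagated
  expect_true(is.na(go_scatter_r2(p, c("a", "b"))$r_squared))
  p3 <- data.frame(gene_id = c("a", "b", "c"), x = c(1, 1, 1), y = c(1, 2, 3))
  expect_match(go_scatter_r2(p3, p3$gene_id)$reason, "variance")
})

test_that("coexpression screen requires significant positive r to both anchors", {
  set.seed(74)
  n_cond <- 20
  anchor <- stats::rnorm(n_cond)
  mat <- rbind(ARF3 = anchor, ARF4 = anchor + stats::rnorm(n_cond, sd = 0.1),
               same = anchor + stats::rnorm(n_cond, sd = 0.05),
               neg = -anchor,
               flat = rep(1, n_cond),
               noise = stats::rnorm(n_cond))
  colnames(mat) <- sprintf("c%02d", seq_len(n_cond))
  res <- coexpression_screen(mat, alpha = 0.01)
  expect_true("same" %in% res$genes)
  expect_false("neg" %in% res$genes)   # r < 0 excluded despite tiny p
  expect_equal(res$excluded, "flat")
  expect_false("ARF3" %in% res$genes)  # anchors excluded from their result
})

test_that("null coexpression pass rate is bounded by alpha squared", {
  set.seed(75)
  n_genes <- 1000; n_cond <- 20; alpha <- 0.01
  mat <- matrix(stats::rnorm((n_genes + 2) * n_cond), ncol = n_cond)
  rownames(mat) <- c("ARF3", "ARF4", sprintf("g%04d", seq_len(n_genes)))
  colnames(mat) <- sprintf("c%02d", seq_len(n_cond))
  res <- coexpression_screen(mat, alpha = alpha)
  # independent profiles: P(pass both one-sided-positive filters) <= alpha^2
  bound <- alpha^2 + 3 * sqrt(alpha^2 * (1 - alpha^2) / n_genes)
  expect_lte(length(res$genes) / n_genes, bound)
})

test_that("delta-delta-Ct follows the exponent laws", {
  ct <- data.frame(sample = c("cal", "s1"),
                   ct_target = c(24, 25), ct_reference = c(20, 20))
  res <- delta_delta_ct(ct, calibrator = "cal")
  expect_equal(res$relative, c(1, 0.5))
  # sample identical to calibrator -> 1
  ct2 <- data.frame(sample = c("cal", "s1"),
                    ct_target = c(24, 24), ct_reference = c(20, 20))
  expect_equal(delta_delta_ct(ct2, "cal")$relative, c(1, 1))
  # lowering target Ct by 1 doubles relative expression
  ct3 <- ct; ct3$ct_target[2] <- 24
  expect_equal(delta_delta_ct(ct3, "cal")$relative[2],
               2 * delta_delta_ct(ct, "cal")$relative[2])
  # missing reference: explicit failure
  ct4 <- ct; ct4$ct_reference[2] <- NA
  expect_error(delta_delta_ct(ct4, "cal"), "s1")
  # simulated Ct tables read back their true relative levels exactly
  tab <- simulate_ct_table(c("a", "b", "c"),
                           relative_level = c(a = 1, b = 0.4, c = 2.5),
                           calibrator = "a")
  back <- delta_delta_ct(tab, calibrator = "a")
  expect_equal(back$relative, c(1, 0.4, 2.5))
})
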