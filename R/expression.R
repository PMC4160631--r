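#' 75th-percentile normalization
#'
#' Divides every sample (column) by its own 75th percentile, computed with
#' the linear-interpolation quantile definition (`stats::quantile` type 7) so
#' normalization is bit-reproducible; afterwards every sample's 75th
#' percentile equals 1. Scalar-multiple samples become identical and already
#' normalized samples are unchanged.
#'
#' @param x A positive intensity matrix (genes x samples) or a
#'   `factorial_matrix`.
#' @return Same shape as the input, normalized.
#' @export
percentile75_normalize <- function(x) {
  mat <- if (inherits(x, "factorial_matrix")) x$exprs else x
  bad <- which(mat <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("nonpositive intensities at (gene, sample): ",
         paste(utils::head(sprintf("(%s, %s)", rownames(mat)[bad[, 1]],
                                   colnames(mat)[bad[, 2]]), 5L),
               collapse = ", "))
  q75 <- apply(mat, 2L, stats::quantile, probs = 0.75, type = 7, names = FALSE)
  out <- sweep(mat, 2L, q75, "/")
  if (inherits(x, "factorial_matrix")) {
    x$exprs <- out
    x
  } else out
}

.design_cells <- function(samples) {
  stopifnot(all(c("genotype", "treatment") %in% colnames(samples)))
  g <- factor(samples$genotype)
  t <- factor(samples$treatment)
  if (nlevels(g) != 2L || nlevels(t) != 2L)
    stop("design must have exactly 2 genotypes and 2 treatments")
  cell <- interaction(g, t, drop = FALSE)
  counts <- table(cell)
  if (length(unique(counts)) != 1L)
    stop("design must be balanced")
  if (counts[1] < 2L)
    stop("each design cell needs >= 2 replicates")
  list(g = g, t = t, cell = cell, r = as.integer(counts[1]))
}

#' Balanced two-way ANOVA per gene (genotype x treatment)
#'
#' Fits genotype + treatment + interaction on log2 intensities for every
#' gene at once using the closed-form balanced-design sums of squares, and
#' tests each term against the residual error (F tests). In a balanced
#' design the sums of squares are order-independent, and permuting replicate
#' order within cells leaves all p-values unchanged. Genes with zero
#' residual variance are flagged degenerate and their p-values set to `NA`
#' rather than propagating NaN.
#'
#' @param fm A `factorial_matrix`, or a positive intensity matrix (genes x
#'   samples) if `samples` is supplied.
#' @param samples Sample sheet with `genotype` and `treatment` columns (taken
#'   from `fm` when it is a `factorial_matrix`).
#' @param log2_transform Analyze `log2(intensity)` (default TRUE; set FALSE
#'   if the matrix is already on the log scale).
#' @return data.frame per gene: `gene_id`, `F_genotype`, `p_genotype`,
#'   `F_treatment`, `p_treatment`, `F_interaction`, `p_interaction`,
#'   `degenerate`.
#' @export
two_way_anova <- function(fm, samples = NULL, log2_transform = TRUE) {
  if (inherits(fm, "factorial_matrix")) {
    samples <- fm$samples
    mat <- fm$exprs
  } else mat <- fm
  d <- .design_cells(samples)
  if (is.null(rownames(mat)))
    rownames(mat) <- sprintf("g%05d", seq_len(nrow(mat)))
  y <- if (log2_transform) log2(mat) else mat
  n <- ncol(y)
  r <- d$r
  xg <- as.integer(d$g) - 1L  # 0/1
  xt <- as.integer(d$t) - 1L
  grand <- rowMeans(y)
  mean_g1 <- rowMeans(y[, xg == 1L, drop = FALSE])
  mean_g0 <- rowMeans(y[, xg == 0L, drop = FALSE])
  mean_t1 <- rowMeans(y[, xt == 1L, drop = FALSE])
  mean_t0 <- rowMeans(y[, xt == 0L, drop = FALSE])
  cells <- list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
  cell_means <- lapply(cells, function(cc)
    rowMeans(y[, xg == cc[1] & xt == cc[2], drop = FALSE]))
  ss_a <- (n / 2) * ((mean_g0 - grand)^2 + (mean_g1 - grand)^2)
  ss_b <- (n / 2) * ((mean_t0 - grand)^2 + (mean_t1 - grand)^2)
  ss_cells <- r * Reduce(`+`, lapply(seq_along(cells), function(i) {
    cc <- cells[[i]]
    gm <- if (cc[1] == 0L) mean_g0 else mean_g1
    tm <- if (cc[2] == 0L) mean_t0 else mean_t1
    (cell_means[[i]] - gm - tm + grand)^2
  }))
  ss_ab <- ss_cells
  fitted <- matrix(0, nrow = nrow(y), ncol = n)
  for (i in seq_along(cells)) {
    cc <- cells[[i]]
    idx <- which(xg == cc[1] & xt == cc[2])
    fitted[, idx] <- cell_means[[i]]
  }
  ss_e <- rowSums((y - fitted)^2)
  df_e <- n - 4L
  ms_e <- ss_e / df_e
  degenerate <- ms_e <= .Machine$double.eps * pmax(1, rowSums(y^2))
  fstat <- function(ss, df) {
    f <- (ss / df) / ms_e
    p <- stats::pf(f, df, df_e, lower.tail = FALSE)
    f[degenerate] <- NA_real_
    p[degenerate] <- NA_real_
    list(f = f, p = p)
  }
  a <- fstat(ss_a, 1L)
  b <- fstat(ss_b, 1L)
  ab <- fstat(ss_ab, 1L)
  data.frame(gene_id = rownames(y),
             F_genotype = a$f, p_genotype = a$p,
             F_treatment = b$f, p_treatment = b$p,
             F_interaction = ab$f, p_interaction = ab$p,
             degenerate = degenerate,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p Numeric vector of p-values in \[0, 1\] (`NA` allowed, propagated).
#' @return q-values, monotone in the p-value ranks.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  stats::p.adjust(p, method = "BH")
}

#' Attach per-factor BH q-values to ANOVA records
#'
#' BH is applied across genes separately for the genotype and treatment
#' factors; significance calls use the two main-effect q-values.
#'
#' @param records data.frame from [two_way_anova()].
#' @param fdr FDR threshold for the flags (default 0.075, strict `<`).
#' @return `records` with `q_genotype`, `q_treatment`, `sig_genotype`,
#'   `sig_treatment` columns added.
#' @export
anova_fdr <- function(records, fdr = 0.075) {
  records$q_genotype <- bh_fdr(records$p_genotype)
  records$q_treatment <- bh_fdr(records$p_treatment)
  records$sig_genotype <- !is.na(records$q_genotype) & records$q_genotype < fdr
  records$sig_treatment <- !is.na(records$q_treatment) & records$q_treatment < fdr
  records
}

#' Venn partition of differentially expressed genes
#'
#' @param records data.frame with `q_genotype`, `q_treatment` (from
#'   [anova_fdr()]) or raw records (q-values are computed at `threshold`).
#' @param threshold FDR threshold (strict `<`).
#' @return Named list `genotype_only`, `treatment_only`, `both`, `total`
#'   (counts; `total` is the number of genes flagged for either factor).
#' @export
venn_partition <- function(records, threshold = 0.075) {
  if (!all(c("q_genotype", "q_treatment") %in% colnames(records)))
    records <- anova_fdr(records, fdr = threshold)
  sg <- !is.na(records$q_genotype) & records$q_genotype < threshold
  st <- !is.na(records$q_treatment) & records$q_treatment < threshold
  list(genotype_only = sum(sg & !st),
       treatment_only = sum(!sg & st),
       both = sum(sg & st),
       total = sum(sg | st))
}

#' Genotype/treatment log2-ratio pairs per gene
#'
#' For each gene, from the four design-cell means of (normalized)
#' intensities: `x = log2((mean rdr6-NS + mean rdr6-D) / (mean WT-NS + mean
#' WT-D))` (genotype axis) and `y = log2((mean WT-D + mean rdr6-D) / (mean
#' WT-NS + mean rdr6-NS))` (treatment axis). Replicate means are computed
#' before summing. Genes with a zero cell mean are excluded and listed.
#'
#' @param fm A `factorial_matrix`, or a matrix with `samples` supplied.
#' @param samples Sample sheet (see [two_way_anova()]).
#' @param genotype_test Level of `genotype` used in the numerator of `x`
#'   (default `"rdr6"`); the other level is the reference.
#' @param treatment_test Level of `treatment` in the numerator of `y`
#'   (default `"drought"`).
#' @return A list with `pairs` (data.frame `gene_id`, `x`, `y`) and
#'   `excluded` (gene ids with zero cell means).
#' @export
genotype_treatment_ratios <- function(fm, samples = NULL,
                                      genotype_test = "rdr6",
                                      treatment_test = "drought") {
  if (inherits(fm, "factorial_matrix")) {
    samples <- fm$samples
    mat <- fm$exprs
  } else mat <- fm
  stopifnot(genotype_test %in% samples$genotype,
            treatment_test %in% samples$treatment)
  g_ref <- setdiff(unique(samples$genotype), genotype_test)
  t_ref <- setdiff(unique(samples$treatment), treatment_test)
  stopifnot(length(g_ref) == 1L, length(t_ref) == 1L)
  cm <- function(g, t) rowMeans(mat[, samples$genotype == g &
                                      samples$treatment == t, drop = FALSE])
  m_test_ref <- cm(genotype_test, t_ref)   # rdr6 nonstressed
  m_test_test <- cm(genotype_test, treatment_test)  # rdr6 drought
  m_ref_ref <- cm(g_ref, t_ref)            # WT nonstressed
  m_ref_test <- cm(g_ref, treatment_test)  # WT drought
  num_x <- m_test_ref + m_test_test
  den_x <- m_ref_ref + m_ref_test
  num_y <- m_ref_test + m_test_test
  den_y <- m_ref_ref + m_test_ref
  ok <- m_test_ref > 0 & m_test_test > 0 & m_ref_ref > 0 & m_ref_test > 0
  pairs <- data.frame(gene_id = rownames(mat)[ok],
                      x = log2(num_x[ok] / den_x[ok]),
                      y = log2(num_y[ok] / den_y[ok]),
                      stringsAsFactors = FALSE, row.names = NULL)
  list(pairs = pairs, excluded = rownames(mat)[!ok])
}

#' Squared correlation of the ratio pair over a GO set
#'
#' R-squared is the squared Pearson correlation of `(x, y)` over the member
#' genes present in the ratio table; the sign of the underlying correlation
#' is reported alongside.
#'
#' @param pairs data.frame `gene_id`, `x`, `y` (from
#'   [genotype_treatment_ratios()]).
#' @param members Gene ids of the GO set.
#' @return A list `r_squared`, `sign` (+1/-1/0), `n` (members used). With
#'   fewer than 3 usable members, or zero variance on either axis,
#'   `r_squared` is `NA` and `reason` explains why.
#' @export
go_scatter_r2 <- function(pairs, members) {
  sub <- pairs[pairs$gene_id %in% members &
                 is.finite(pairs$x) & is.finite(pairs$y), , drop = FALSE]
  if (nrow(sub) < 3L)
    return(list(r_squared = NA_real_, sign = NA_integer_, n = nrow(sub),
                reason = "fewer than 3 usable member genes"))
  if (stats::sd(sub$x) == 0 || stats::sd(sub$y) == 0)
    return(list(r_squared = NA_real_, sign = NA_integer_, n = nrow(sub),
                reason = "zero variance on one axis"))
  r <- stats::cor(sub$x, sub$y)
  list(r_squared = r^2, sign = sign(r), n = nrow(sub), reason = NULL)
}

#' Coexpression screen against anchor genes
#'
#' For every gene, the Pearson correlation with each anchor across
#' conditions is tested two-sided (`stats::cor.test`); a gene passes when it
#' is significantly (p < `alpha`) positively correlated with every anchor.
#' Anchors are excluded from their own result; constant-profile genes are
#' excluded and listed.
#'
#' @param mat Expression matrix (genes x conditions), >= 10 conditions.
#' @param anchors Anchor gene ids (default `c("ARF3", "ARF4")`), present in
#'   `mat`.
#' @param alpha Per-anchor significance threshold (default 0.01, strict `<`).
#' @return A list with `genes` (passing gene ids), `table` (per-gene `r` and
#'   `p` against every anchor) and `excluded` (constant-profile gene ids).
#' @export
coexpression_screen <- function(mat, anchors = c("ARF3", "ARF4"),
                                alpha = 0.01) {
  stopifnot(ncol(mat) >= 10L, all(anchors %in% rownames(mat)))
  candidates <- setdiff(rownames(mat), anchors)
  sds <- apply(mat[candidates, , drop = FALSE], 1L, stats::sd)
  excluded <- candidates[sds == 0]
  candidates <- candidates[sds > 0]
  res <- data.frame(gene_id = candidates, stringsAsFactors = FALSE)
  pass <- rep(TRUE, length(candidates))
  for (a in anchors) {
    aprof <- mat[a, ]
    if (stats::sd(aprof) == 0) stop("anchor '", a, "' has a constant profile")
    r <- numeric(length(candidates))
    p <- numeric(length(candidates))
    for (i in seq_along(candidates)) {
      ct <- stats::cor.test(mat[candidates[i], ], aprof,
                            method = "pearson", alternative = "two.sided")
      r[i] <- unname(ct$estimate)
      p[i] <- ct$p.value
    }
    res[[paste0("r_", a)]] <- r
    res[[paste0("p_", a)]] <- p
    pass <- pass & (p < alpha) & (r > 0)
  }
  list(genes = candidates[pass], table = res, excluded = excluded)
}

#' Delta-delta-Ct relative quantification
#'
#' `dCt = Ct_target - Ct_reference`, `ddCt = dCt_sample - dCt_calibrator`,
#' relative expression `= 2^(-ddCt)`; the calibrator's relative expression is
#' 1 by construction, and lowering a sample's target Ct by one cycle doubles
#' its relative expression.
#'
#' @param ct data.frame with columns `sample`, `ct_target`, `ct_reference`.
#' @param calibrator Calibrator sample id.
#' @return `ct` with `delta_ct`, `delta_delta_ct` and `relative` columns.
#' @export
delta_delta_ct <- function(ct, calibrator) {
  stopifnot(all(c("sample", "ct_target", "ct_reference") %in% colnames(ct)),
            calibrator %in% ct$sample)
  if (anyNA(ct$ct_reference))
    stop("missing reference Ct for sample(s): ",
         paste(ct$sample[is.na(ct$ct_reference)], collapse = ", "))
  if (anyNA(ct$ct_target))
    stop("missing target Ct for sample(s): ",
         paste(ct$sample[is.na(ct$ct_target)], collapse = ", "))
  dct <- ct$ct_target - ct$ct_reference
  ddct <- dct - dct[match(calibrator, ct$sample)]
  ct$delta_ct <- dct
  ct$delta_delta_ct <- ddct
  ct$relative <- 2^(-ddct)
  ct
}
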