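#' Specification of a synthetic factorial expression experiment
#'
#' Emulates a 2 genotypes (WT, rdr6) x 2 treatments (nonstressed, drought)
#' design with replicated arrays. Per-gene log2 effects may be supplied
#' explicitly; genes belonging to a GO set draw their (genotype, treatment)
#' effect pair from a bivariate normal with a planted correlation rho, the
#' device used to emulate coupled genotype/treatment response within a
#' functional category.
#'
#' @param n_genes Number of genes.
#' @param n_replicates Replicates per design cell (>= 2; default 3).
#' @param baseline_mean,baseline_sd Log2 baseline intensity distribution.
#' @param genotype_effect,treatment_effect,interaction_effect Per-gene log2
#'   effects, recycled to `n_genes` (default 0).
#' @param noise_sd Residual log2 noise standard deviation (> 0).
#' @param go_sets Optional data.frame with columns `term`, `size`, `rho`,
#'   `effect_sd` describing GO sets; sets are assigned disjoint gene blocks
#'   in order and their members' genotype/treatment effects are drawn from a
#'   bivariate normal with sd `effect_sd` and correlation `rho`.
#' @param seed Integer seed.
#' @return A list of class `expression_effect_spec`.
#' @export
expression_effect_spec <- function(n_genes = 1000L,
                                   n_replicates = 3L,
                                   baseline_mean = 8,
                                   baseline_sd = 1.5,
                                   genotype_effect = 0,
                                   treatment_effect = 0,
                                   interaction_effect = 0,
                                   noise_sd = 0.25,
                                   go_sets = NULL,
                                   seed = 1L) {
  stopifnot(n_genes >= 1L, n_replicates >= 2L, noise_sd > 0)
  if (!is.null(go_sets)) {
    stopifnot(is.data.frame(go_sets),
              all(c("term", "size", "rho", "effect_sd") %in% colnames(go_sets)),
              all(abs(go_sets$rho) <= 1), all(go_sets$size >= 3),
              sum(go_sets$size) <= n_genes)
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_replicates = as.integer(n_replicates),
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 genotype_effect = rep_len(genotype_effect, n_genes),
                 treatment_effect = rep_len(treatment_effect, n_genes),
                 interaction_effect = rep_len(interaction_effect, n_genes),
                 noise_sd = noise_sd, go_sets = go_sets,
                 seed = as.integer(seed)),
            class = "expression_effect_spec")
}

# bivariate normal pairs with correlation rho (exact construction)
.bivariate_effects <- function(n, sd, rho) {
  x <- stats::rnorm(n, sd = sd)
  z <- stats::rnorm(n, sd = sd)
  y <- rho * x + sqrt(max(0, 1 - rho^2)) * z
  cbind(x, y)
}

#' Simulate a factorial expression matrix with ground truth
#'
#' Intensities are `2^(baseline + g*x_g + t*x_t + i*x_g*x_t + noise)` with
#' indicator coding `x_g = 1` for rdr6 and `x_t = 1` for drought, so a
#' genotype effect of +1 log2 doubles the rdr6 cell means relative to WT.
#'
#' @param eff An [expression_effect_spec()].
#' @return A list of class `factorial_matrix` with elements `exprs` (genes x
#'   samples intensity matrix, all positive), `samples` (data.frame with
#'   `sample`, `genotype`, `treatment`, `replicate`), `go_memberships`
#'   (data.frame `term`, `gene_id`; empty if no GO sets), and `truth`
#'   (per-gene true log2 effects).
#' @export
simulate_expression_matrix <- function(eff) {
  stopifnot(inherits(eff, "expression_effect_spec"))
  set.seed(eff$seed)
  n <- eff$n_genes
  gene_ids <- sprintf("g%05d", seq_len(n))
  g_eff <- eff$genotype_effect
  t_eff <- eff$treatment_effect
  i_eff <- eff$interaction_effect
  go_rows <- list()
  if (!is.null(eff$go_sets)) {
    at <- 1L
    for (j in seq_len(nrow(eff$go_sets))) {
      sz <- eff$go_sets$size[j]
      idx <- seq.int(at, at + sz - 1L)
      at <- at + sz
      pair <- .bivariate_effects(sz, eff$go_sets$effect_sd[j],
                                 eff$go_sets$rho[j])
      g_eff[idx] <- pair[, 1]
      t_eff[idx] <- pair[, 2]
      go_rows[[j]] <- data.frame(term = eff$go_sets$term[j],
                                 gene_id = gene_ids[idx],
                                 stringsAsFactors = FALSE)
    }
  }
  go_memberships <- if (length(go_rows) > 0L) do.call(rbind, go_rows) else
    data.frame(term = character(0), gene_id = character(0))

  genotype <- rep(c("WT", "rdr6"), each = 2L * eff$n_replicates)
  treatment <- rep(rep(c("nonstressed", "drought"), each = eff$n_replicates), 2L)
  replicate <- rep(seq_len(eff$n_replicates), 4L)
  samples <- data.frame(
    sample = sprintf("%s_%s_r%d", genotype,
                     ifelse(treatment == "drought", "D", "NS"), replicate),
    genotype = genotype, treatment = treatment, replicate = replicate,
    stringsAsFactors = FALSE)
  x_g <- as.numeric(genotype == "rdr6")
  x_t <- as.numeric(treatment == "drought")
  baseline <- stats::rnorm(n, eff$baseline_mean, eff$baseline_sd)
  mu <- outer(baseline, rep(1, nrow(samples))) +
    outer(g_eff, x_g) + outer(t_eff, x_t) + outer(i_eff, x_g * x_t)
  noise <- matrix(stats::rnorm(n * nrow(samples), sd = eff$noise_sd),
                  nrow = n)
  exprs <- 2^(mu + noise)
  dimnames(exprs) <- list(gene_ids, samples$sample)
  structure(list(exprs = exprs, samples = samples,
                 go_memberships = go_memberships,
                 truth = data.frame(gene_id = gene_ids,
                                    genotype_effect = g_eff,
                                    treatment_effect = t_eff,
                                    interaction_effect = i_eff,
                                    baseline = baseline,
                                    stringsAsFactors = FALSE)),
            class = "factorial_matrix")
}

#' @export
print.factorial_matrix <- function(x, ...) {
  cat("factorial_matrix:", nrow(x$exprs), "genes x", ncol(x$exprs),
      "samples (", paste(unique(x$samples$genotype), collapse = "/"), "x",
      paste(unique(x$samples$treatment), collapse = "/"), ")\n")
  invisible(x)
}

#' Simulate a qPCR Ct table
#'
#' Generates target and reference Ct values per sample from true relative
#' expression levels; one cycle difference corresponds to a two-fold change,
#' so the delta-delta-Ct readback recovers `relative_level` exactly up to the
#' simulated measurement noise.
#'
#' @param sample_ids Sample identifiers; the first is the calibrator unless
#'   `calibrator` is given.
#' @param relative_level Named true relative expression per sample
#'   (calibrator = 1).
#' @param reference_ct Mean reference-gene Ct (default 20, e.g. ACT2/U2).
#' @param target_base_ct Target-gene Ct in the calibrator sample.
#' @param noise_sd Ct measurement noise (default 0 for exact tables).
#' @param calibrator Calibrator sample id.
#' @param seed Integer seed.
#' @return data.frame `sample`, `ct_target`, `ct_reference` plus attribute-free
#'   `calibrator` column marking the calibrator sample.
#' @export
simulate_ct_table <- function(sample_ids,
                              relative_level = stats::setNames(rep(1, length(sample_ids)), sample_ids),
                              reference_ct = 20,
                              target_base_ct = 25,
                              noise_sd = 0,
                              calibrator = sample_ids[1],
                              seed = 1L) {
  stopifnot(all(sample_ids %in% names(relative_level)),
            calibrator %in% sample_ids, noise_sd >= 0)
  set.seed(seed)
  rel <- relative_level[sample_ids] / relative_level[[calibrator]]
  ct_ref <- reference_ct + stats::rnorm(length(sample_ids), sd = noise_sd)
  # relative = 2^-(ddCt): higher expression -> lower target Ct
  ct_tgt <- target_base_ct - log2(rel) + (ct_ref - reference_ct) +
    stats::rnorm(length(sample_ids), sd = noise_sd)
  data.frame(sample = sample_ids, ct_target = as.numeric(ct_tgt),
             ct_reference = as.numeric(ct_ref),
             calibrator = sample_ids == calibrator,
             stringsAsFactors = FALSE)
}
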