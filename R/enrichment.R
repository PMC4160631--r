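#' Normalize family counts against per-library miRNA totals
#'
#' RNA degradation fragments inflate raw library sizes unevenly, so family
#' abundances are normalized by dividing by the total number of miRNA reads
#' obtained in the same library (no additional scaling), and expressed
#' relative to the control library.
#'
#' @param fam_counts Integer matrix families x libraries.
#' @param mirna_totals Named per-library totals of miRNA-classified reads;
#'   all must be > 0.
#' @param control Control library label.
#' @return data.frame with one row per (family, library): `family`,
#'   `library`, `count`, `mirna_total`, `normalized` (= count/mirna_total)
#'   and `relative` (= normalized / control normalized; `NA` when the control
#'   count is 0, never infinity).
#' @export
normalize_by_mirna <- function(fam_counts, mirna_totals, control) {
  libs <- colnames(fam_counts)
  stopifnot(all(libs %in% names(mirna_totals)), control %in% libs)
  zero <- libs[mirna_totals[libs] <= 0]
  if (length(zero) > 0L)
    stop("miRNA total is zero in library: ", paste(zero, collapse = ", "))
  norm <- sweep(fam_counts, 2L, mirna_totals[libs], "/")
  ctrl <- norm[, control]
  rel <- sweep(norm, 1L, ifelse(ctrl > 0, ctrl, NA_real_), "/")
  data.frame(
    family = rep(rownames(fam_counts), times = length(libs)),
    library = rep(libs, each = nrow(fam_counts)),
    count = as.vector(fam_counts),
    mirna_total = rep(unname(mirna_totals[libs]), each = nrow(fam_counts)),
    normalized = as.vector(norm),
    relative = as.vector(rel),
    stringsAsFactors = FALSE)
}

#' Exact hypergeometric tail probabilities for a 2x2 count table
#'
#' For `X ~ Hypergeometric(N, K, n)` (population `N`, successes `K`, draws
#' `n`), returns the exact tail sums `p_up = P(X >= k)` and
#' `p_down = P(X <= k)`. Vectorized over its arguments.
#'
#' @param k Observed successes in the draw.
#' @param n Draw size.
#' @param K Successes in the population.
#' @param N Population size.
#' @return data.frame with columns `p_up` and `p_down`.
#' @export
hypergeom_enrichment <- function(k, n, K, N) {
  bad <- k < 0 | k > pmin(n, K) | n > N | K > N | k < n - (N - K)
  if (any(bad))
    stop("inconsistent hypergeometric margins at index ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  data.frame(
    p_up = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
    p_down = stats::phyper(k, K, N - K, n))
}

#' Hypergeometric stress-enrichment of families against the control library
#'
#' Builds one 2x2 table per (family, stress library): the stress column
#' against the pooled stress+control population, with the miRNA pool as the
#' reference counts. For a miRNA family (contained in the miRNA pool) the
#' margins are `k` = family count in the stress library, `n` = the library's
#' miRNA total, `K`/`N` = the pooled analogues. A non-miRNA unit (a ta-siRNA
#' family) is not contained in the miRNA pool, so its population is unit +
#' miRNA reads: `n = k +` miRNA total and `N = K +` pooled miRNA total.
#'
#' @param fam_counts Integer matrix families x libraries.
#' @param family_class Named vector per family (`"MIRNA"`/`"TAS"`).
#' @param mirna_totals Named per-library miRNA read totals.
#' @param control Control library label.
#' @param stress_libraries Stress libraries (default: all but the control).
#' @param alpha Significance threshold (strict `<`) for flagging.
#' @return data.frame with one row per (family, stress library): margins
#'   `k`, `n`, `K`, `N`, tails `p_up`/`p_down`, `significant`, `direction`
#'   (`"up"`, `"down"` or `"none"`).
#' @export
enrich_families <- function(fam_counts, family_class, mirna_totals, control,
                            stress_libraries = NULL, alpha = 1e-3) {
  libs <- colnames(fam_counts)
  stopifnot(control %in% libs, all(rownames(fam_counts) %in% names(family_class)))
  if (is.null(stress_libraries)) stress_libraries <- setdiff(libs, control)
  rows <- list()
  for (lib in stress_libraries) {
    k <- fam_counts[, lib]
    kc <- fam_counts[, control]
    is_mir <- family_class[rownames(fam_counts)] == "MIRNA"
    n <- ifelse(is_mir, mirna_totals[[lib]], k + mirna_totals[[lib]])
    N <- ifelse(is_mir, mirna_totals[[lib]] + mirna_totals[[control]],
                k + kc + mirna_totals[[lib]] + mirna_totals[[control]])
    K <- k + kc
    rows[[lib]] <- data.frame(
      family = rownames(fam_counts), library = lib,
      k = as.integer(k), n = as.integer(n),
      K = as.integer(K), N = as.integer(N),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res <- cbind(res, hypergeom_enrichment(res$k, res$n, res$K, res$N))
  call_stress_responsive(res, alpha = alpha)
}

#' Flag stress-responsive families
#'
#' A family is flagged up in a library when `p_up < alpha` and down when
#' `p_down < alpha` (strict inequality: a tail probability exactly equal to
#' the threshold is not flagged).
#'
#' @param results data.frame with `p_up` and `p_down` columns.
#' @param alpha Significance threshold (default 1e-3).
#' @return `results` with added `significant` (logical) and `direction`
#'   (`"up"`, `"down"`, `"none"`) columns.
#' @export
call_stress_responsive <- function(results, alpha = 1e-3) {
  stopifnot(all(c("p_up", "p_down") %in% colnames(results)))
  up <- results$p_up < alpha
  down <- results$p_down < alpha
  results$significant <- up | down
  results$direction <- ifelse(up & !down, "up",
                       ifelse(down & !up, "down",
                       ifelse(up & down, "both", "none")))
  results
}
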