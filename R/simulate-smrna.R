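#' Default small-RNA library labels
#'
#' Seven libraries: three stresses (drought, cold, high salinity) sampled in
#' two pooled time windows each, plus a nonstressed control.
#' @return Character vector of library labels.
#' @export
smrna_library_labels <- function() {
  c("drought_1_5h", "drought_6_10h", "cold_1_5h", "cold_6_10h",
    "salt_1_5h", "salt_6_10h", "no_treatment")
}

.default_length_probs <- stats::setNames(
  c(0.03, 0.03, 0.03, 0.03, 0.30, 0.07, 0.08, 0.25,
    0.06, 0.04, 0.03, 0.02, 0.015, 0.015),
  as.character(17:30))

.default_class_weights <- c(MIRNA = 2, TAS = 1.5, TE_gene = 0.6,
                            pseudogene = 0.4, intergenic_TE = 0.5,
                            tRNA = 0.3, rRNA = 0.5, snoRNA = 0.2,
                            snRNA = 0.2, protein_coding_gene = 0)

#' Specification of stress-shifted small-RNA libraries
#'
#' Encodes the emission model: per-locus baseline abundance weights, a
#' fold-change map applying treatment-specific multipliers to locus classes
#' or individual loci, per-library fractions of sense-strand mRNA degradation
#' fragments and of random intergenic background, the sequencing depth, and
#' the read-length distribution over 17-30 nt. Defaults encode the study
#' conditions: phased TAS siRNAs strongly downregulated under drought and
#' high salinity (multiplier 0.3, mildly under cold), and elevated mRNA
#' degradation under drought/salt (15% of reads vs 5% in the control).
#'
#' @param libraries Library labels.
#' @param depth Reads per library (scalar or named per-library vector).
#' @param class_weights Named nonnegative weights per feature category; every
#'   locus of a category inherits its weight as baseline abundance.
#' @param locus_weights Optional named vector of per-locus baseline weights
#'   overriding the class weight for those loci.
#' @param fold_changes `data.frame(library, target, multiplier)`; `target` is
#'   `"class:<category>"` or `"locus:<ID>"`. Multipliers for a library
#'   multiply the matching baseline weights before multinomial sampling.
#' @param degradation_fraction Named per-library fraction (in \[0,1\]) of reads
#'   drawn as sense-strand fragments of protein-coding genes.
#' @param background_fraction Fraction of reads drawn from random intergenic
#'   positions (populates the "other intergenic" composition class).
#' @param length_probs Named probability vector over read lengths 17-30;
#'   miRNA and TAS emissions are always exactly 21 nt.
#' @param seed Integer seed.
#' @return A list of class `smrna_effect_spec`.
#' @export
smrna_effect_spec <- function(libraries = smrna_library_labels(),
                              depth = 20000L,
                              class_weights = .default_class_weights,
                              locus_weights = NULL,
                              fold_changes = default_stress_fold_changes(libraries),
                              degradation_fraction = default_degradation_fractions(libraries),
                              background_fraction = 0.05,
                              length_probs = .default_length_probs,
                              seed = 1L) {
  if (length(depth) == 1L) depth <- stats::setNames(rep(depth, length(libraries)), libraries)
  stopifnot(all(libraries %in% names(depth)))
  if (any(depth <= 0)) stop("library depth must be > 0")
  if (length(degradation_fraction) == 1L)
    degradation_fraction <- stats::setNames(
      rep(degradation_fraction, length(libraries)), libraries)
  stopifnot(all(libraries %in% names(degradation_fraction)),
            all(degradation_fraction >= 0), all(degradation_fraction <= 1),
            background_fraction >= 0, background_fraction <= 1,
            all(class_weights >= 0),
            is.null(locus_weights) || all(locus_weights >= 0),
            abs(sum(length_probs) - 1) < 1e-8,
            all(names(length_probs) %in% as.character(17:30)))
  if (!is.null(fold_changes))
    stopifnot(is.data.frame(fold_changes),
              all(c("library", "target", "multiplier") %in% colnames(fold_changes)),
              all(fold_changes$multiplier >= 0))
  structure(list(libraries = libraries, depth = depth[libraries],
                 class_weights = class_weights, locus_weights = locus_weights,
                 fold_changes = fold_changes,
                 degradation_fraction = degradation_fraction[libraries],
                 background_fraction = background_fraction,
                 length_probs = length_probs, seed = as.integer(seed)),
            class = "smrna_effect_spec")
}

#' Default fold-change map: TAS downregulation under drought and salinity
#' @param libraries Library labels.
#' @return `data.frame(library, target, multiplier)`.
#' @export
default_stress_fold_changes <- function(libraries = smrna_library_labels()) {
  stress <- setdiff(libraries, "no_treatment")
  mult <- ifelse(grepl("^cold", stress), 0.7, 0.3)
  data.frame(library = stress, target = "class:TAS", multiplier = mult,
             stringsAsFactors = FALSE)
}

#' Default degradation fractions: elevated under drought and high salinity
#' @param libraries Library labels.
#' @return Named numeric vector.
#' @export
default_degradation_fractions <- function(libraries = smrna_library_labels()) {
  f <- ifelse(libraries == "no_treatment", 0.05,
              ifelse(grepl("^cold", libraries), 0.06, 0.15))
  stats::setNames(f, libraries)
}

.sample_lengths <- function(n, length_probs, max_len = 30L) {
  lens <- as.integer(names(length_probs))
  keep <- lens <= max_len
  sample(lens[keep], n, replace = TRUE, prob = length_probs[keep])
}

# vectorized sequence extraction for a read table (chrom, start, end, strand)
.extract_reads <- function(chrom_chars, tab) {
  if (nrow(tab) == 0L) return(character(0))
  out <- character(nrow(tab))
  for (ch in unique(tab$chrom)) {
    idx <- which(tab$chrom == ch)
    out[idx] <- substring(chrom_chars[[ch]], tab$start[idx], tab$end[idx])
  }
  minus <- which(tab$strand == "-")
  if (length(minus) > 0L)
    out[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(out[minus])))
  out
}

#' Simulate stress-shifted small-RNA read libraries
#'
#' Each library is a multiset of reads sampled multinomially from locus
#' emissions (baseline weights times any matching fold-change multipliers),
#' plus sense-strand mRNA degradation fragments and random intergenic
#' background, summing exactly to the requested depth. MIRNA loci emit their
#' stored 21 nt mature sequence; TAS loci emit 21 nt reads cut in phase from
#' the stored phase-start; all other emissions draw lengths from the spec's
#' 17-30 nt distribution.
#'
#' @param genome An `annotated_genome`.
#' @param eff An [smrna_effect_spec()].
#' @return A list with `reads` (named list, one character vector of read
#'   sequences per library), `read_origins` (per-library data.frame of
#'   chrom/start/strand/origin), and `truth` (sampled per-origin counts per
#'   library as a matrix, plus the expected emission proportions).
#' @export
simulate_smrna_libraries <- function(genome, eff) {
  stopifnot(inherits(genome, "annotated_genome"),
            inherits(eff, "smrna_effect_spec"))
  set.seed(eff$seed)
  feats <- genome$features
  mc <- S4Vectors::mcols(feats)
  ids <- mc$ID
  types <- mc$type
  if (!is.null(eff$fold_changes)) {
    tgt <- eff$fold_changes$target
    cls <- sub("^class:", "", tgt[startsWith(tgt, "class:")])
    loc <- sub("^locus:", "", tgt[startsWith(tgt, "locus:")])
    bad <- c(setdiff(cls, feature_categories()), setdiff(loc, ids))
    if (length(bad) > 0L)
      stop("fold-change targets not found in genome/annotation: ",
           paste(bad, collapse = ", "))
    if (!all(startsWith(tgt, "class:") | startsWith(tgt, "locus:")))
      stop("fold-change targets must be 'class:<category>' or 'locus:<ID>'")
  }
  w <- unname(eff$class_weights[types])
  w[is.na(w)] <- 0
  if (!is.null(eff$locus_weights)) {
    hit <- match(names(eff$locus_weights), ids)
    if (anyNA(hit)) stop("locus_weights name unknown locus")
    w[hit] <- unname(eff$locus_weights)
  }
  pc <- which(types == "protein_coding_gene")
  chrom_chars <- lapply(genome$seqs, as.character)
  chrom_lens <- Biostrings::width(genome$seqs)
  names(chrom_lens) <- names(genome$seqs)

  origin_names <- c(ids, "degradation", "background")
  truth_counts <- matrix(0L, nrow = length(origin_names),
                         ncol = length(eff$libraries),
                         dimnames = list(origin_names, eff$libraries))
  expected_props <- truth_counts
  reads <- vector("list", length(eff$libraries))
  origins <- vector("list", length(eff$libraries))
  names(reads) <- names(origins) <- eff$libraries

  for (lib in eff$libraries) {
    mult <- rep(1, length(feats))
    fc <- eff$fold_changes
    if (!is.null(fc)) {
      fc <- fc[fc$library == lib, , drop = FALSE]
      for (j in seq_len(nrow(fc))) {
        tg <- fc$target[j]
        if (startsWith(tg, "class:")) {
          mult[types == sub("^class:", "", tg)] <-
            mult[types == sub("^class:", "", tg)] * fc$multiplier[j]
        } else {
          mult[ids == sub("^locus:", "", tg)] <-
            mult[ids == sub("^locus:", "", tg)] * fc$multiplier[j]
        }
      }
    }
    lw <- w * mult
    d <- eff$degradation_fraction[[lib]]
    b <- eff$background_fraction
    if (d + b > 1) stop("degradation + background fraction exceeds 1 for ", lib)
    locus_mass <- 1 - d - b
    if (sum(lw) == 0 && locus_mass > 0) {
      if (d + b == 0) stop("all locus weights zero and no degradation/background mass")
      # renormalize onto degradation/background only
      probs <- c(rep(0, length(lw)), d, b) / (d + b)
    } else {
      locus_probs <- if (sum(lw) > 0) lw / sum(lw) * locus_mass else rep(0, length(lw))
      probs <- c(locus_probs, d, b)
    }
    expected_props[, lib] <- probs
    counts <- as.integer(stats::rmultinom(1, eff$depth[[lib]], probs))
    truth_counts[, lib] <- counts

    tabs <- list()
    for (k in which(counts[seq_along(feats)] > 0L)) {
      n <- counts[k]
      fstart <- GenomicRanges::start(feats)[k]
      fend <- GenomicRanges::end(feats)[k]
      fstrand <- as.character(BiocGenerics::strand(feats))[k]
      fchrom <- as.character(GenomeInfoDb::seqnames(feats))[k]
      if (types[k] == "MIRNA") {
        ms <- mc$mature_start[k]
        starts <- rep(ms, n)
        ends <- starts + 20L
      } else if (types[k] == "TAS") {
        ps <- mc$phase_start[k]
        phase_starts <- seq.int(ps, fend - 20L, by = 21L)
        starts <- sample(phase_starts, n, replace = TRUE)
        ends <- starts + 20L
      } else {
        lens <- .sample_lengths(n, eff$length_probs,
                                max_len = min(30L, fend - fstart + 1L))
        starts <- fstart + floor(stats::runif(n) * (fend - fstart + 2L - lens))
        starts <- pmin(pmax(starts, fstart), fend - lens + 1L)
        ends <- starts + lens - 1L
      }
      tabs[[length(tabs) + 1L]] <- data.frame(
        chrom = fchrom, start = as.integer(starts), end = as.integer(ends),
        strand = fstrand, origin = ids[k], stringsAsFactors = FALSE)
    }
    n_deg <- counts[length(feats) + 1L]
    if (n_deg > 0L) {
      if (length(pc) == 0L) stop("degradation fraction > 0 but no protein-coding genes")
      gidx <- sample(pc, n_deg, replace = TRUE)
      lens <- .sample_lengths(n_deg, eff$length_probs)
      gs <- GenomicRanges::start(feats)[gidx]
      ge <- GenomicRanges::end(feats)[gidx]
      lens <- pmin(lens, ge - gs + 1L)
      starts <- gs + floor(stats::runif(n_deg) * (ge - gs + 2L - lens))
      starts <- pmin(pmax(starts, gs), ge - lens + 1L)
      tabs[[length(tabs) + 1L]] <- data.frame(
        chrom = as.character(GenomeInfoDb::seqnames(feats))[gidx],
        start = as.integer(starts), end = as.integer(starts + lens - 1L),
        strand = as.character(BiocGenerics::strand(feats))[gidx],
        origin = "degradation", stringsAsFactors = FALSE)
    }
    n_bg <- counts[length(feats) + 2L]
    if (n_bg > 0L) {
      # batched rejection sampling of intergenic positions
      acc <- list()
      need <- n_bg
      for (try in seq_len(50L)) {
        m <- max(need * 2L, 100L)
        len <- .sample_lengths(m, eff$length_probs)
        ch <- sample(names(chrom_lens), m, replace = TRUE)
        st <- floor(stats::runif(m) * (chrom_lens[ch] - len + 1L)) + 1L
        cand <- GenomicRanges::GRanges(ch, IRanges::IRanges(st, st + len - 1L))
        ok <- if (length(feats) == 0L) rep(TRUE, m) else
          !IRanges::overlapsAny(cand, feats, ignore.strand = TRUE)
        take <- utils::head(which(ok), need)
        if (length(take) > 0L) {
          acc[[length(acc) + 1L]] <- data.frame(
            chrom = unname(ch[take]), start = as.integer(st[take]),
            end = as.integer(st[take] + len[take] - 1L),
            strand = sample(c("+", "-"), length(take), replace = TRUE),
            origin = "background", stringsAsFactors = FALSE)
          need <- need - length(take)
        }
        if (need <= 0L) break
      }
      if (need > 0L)
        stop("could not sample intergenic background reads (genome too dense)")
      tabs[[length(tabs) + 1L]] <- do.call(rbind, acc)
    }
    tab <- if (length(tabs) > 0L) do.call(rbind, tabs) else
      data.frame(chrom = character(0), start = integer(0), end = integer(0),
                 strand = character(0), origin = character(0))
    tab$sequence <- .extract_reads(chrom_chars, tab)
    reads[[lib]] <- tab$sequence
    origins[[lib]] <- tab
  }
  list(reads = reads, read_origins = origins,
       truth = list(counts = truth_counts, expected_props = expected_props))
}
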