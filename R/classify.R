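#' Classification categories, in precedence order
#'
#' Dedicated small-RNA loci come first so that a signature hitting both a
#' MIRNA locus and a gene is called miRNA; the wedges of the composition
#' table are therefore mutually exclusive.
#' @return Character vector, highest precedence first.
#' @export
classification_categories <- function() {
  c("miRNA", "ta_siRNA", "protein_coding_sense", "protein_coding_antisense",
    "TE_gene", "pseudogene", "intergenic_TE", "other_intergenic")
}

#' Classify mapped signatures by genomic category
#'
#' Each signature receives exactly one category, evaluated over all of its
#' hits: every hit is assigned the category of the features it overlaps
#' (>= 1 nt overlap, any strand, except that protein-coding overlap is split
#' into sense / antisense by strand agreement), and the highest-precedence
#' category among all hits wins. Hits overlapping no feature fall through to
#' `other_intergenic`. Structural RNA features are ignored here; remove their
#' signatures first with [filter_structural()].
#'
#' @param hits `GRanges` of mapped hits with `signature_id`.
#' @param annotation `GRanges` of features with `type` (and `ID`) columns.
#' @return data.frame with `signature_id` and `category`.
#' @export
classify_signatures <- function(hits, annotation) {
  stopifnot(inherits(hits, "GRanges"),
            "signature_id" %in% colnames(S4Vectors::mcols(hits)))
  cats <- classification_categories()
  sig <- S4Vectors::mcols(hits)$signature_id
  n <- length(hits)
  rank <- rep.int(match("other_intergenic", cats), n)
  feats <- annotation[!(S4Vectors::mcols(annotation)$type %in%
                          structural_categories())]
  if (length(feats) > 0L && n > 0L) {
    ov <- GenomicRanges::findOverlaps(hits, feats, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    ftype <- S4Vectors::mcols(feats)$type[sh]
    same_strand <- as.character(BiocGenerics::strand(hits))[qh] ==
      as.character(BiocGenerics::strand(feats))[sh]
    ovcat <- ifelse(ftype == "MIRNA", "miRNA",
             ifelse(ftype == "TAS", "ta_siRNA",
             ifelse(ftype == "protein_coding_gene",
                    ifelse(same_strand, "protein_coding_sense",
                           "protein_coding_antisense"),
                    ftype)))
    ovrank <- match(ovcat, cats)
    best <- tapply(ovrank, qh, min)
    idx <- as.integer(names(best))
    rank[idx] <- pmin(rank[idx], as.integer(best))
  }
  best_by_sig <- tapply(rank, sig, min)
  data.frame(signature_id = names(best_by_sig),
             category = cats[as.integer(best_by_sig)],
             stringsAsFactors = FALSE)
}

#' Tabulate per-library composition by category
#'
#' Read-count-weighted category totals and percentages per library;
#' percentages per library sum to 100 (all-zero libraries are flagged and
#' reported as zero rows).
#'
#' @param classes data.frame from [classify_signatures()].
#' @param counts Integer matrix signatures x libraries (rownames signature
#'   ids); signatures absent from `classes` (e.g. unmapped) are ignored.
#' @return A list with `counts` (matrix category x library), `percentages`
#'   (same shape) and `empty_libraries` (labels with zero mapped reads).
#' @export
tabulate_composition <- function(classes, counts) {
  cats <- classification_categories()
  libs <- colnames(counts)
  cm <- matrix(0, nrow = length(cats), ncol = length(libs),
               dimnames = list(cats, libs))
  idx <- match(classes$signature_id, rownames(counts))
  ok <- !is.na(idx)
  for (j in seq_along(libs)) {
    v <- tapply(counts[idx[ok], j], classes$category[ok], sum)
    cm[names(v), j] <- v
  }
  tot <- colSums(cm)
  pct <- sweep(cm, 2L, ifelse(tot > 0, tot, 1), "/") * 100
  pct[, tot == 0] <- 0
  list(counts = cm, percentages = pct,
       empty_libraries = libs[tot == 0])
}

#' Assign miRNA / ta-siRNA signatures to their locus family
#'
#' A family is a MIRNA or TAS feature. Each signature classified `miRNA`
#' (`ta_siRNA`) is assigned to the MIRNA (TAS) feature its hits overlap; a
#' multi-family signature is assigned once, to the first overlapped feature
#' in genome order (deterministic).
#'
#' @param hits `GRanges` of mapped hits with `signature_id`.
#' @param annotation `GRanges` of features with `ID` and `type`.
#' @param classes data.frame from [classify_signatures()].
#' @return data.frame `signature_id`, `family` (feature ID), `family_class`
#'   (`"MIRNA"` or `"TAS"`); one row per miRNA/ta-siRNA signature.
#' @export
assign_families <- function(hits, annotation, classes) {
  out <- list()
  for (fc in c("MIRNA", "TAS")) {
    want_cat <- if (fc == "MIRNA") "miRNA" else "ta_siRNA"
    sigs <- classes$signature_id[classes$category == want_cat]
    if (length(sigs) == 0L) next
    feats <- annotation[S4Vectors::mcols(annotation)$type == fc]
    sub <- hits[S4Vectors::mcols(hits)$signature_id %in% sigs]
    ov <- GenomicRanges::findOverlaps(sub, feats, ignore.strand = TRUE)
    if (length(ov) == 0L) next
    df <- data.frame(
      signature_id = S4Vectors::mcols(sub)$signature_id[S4Vectors::queryHits(ov)],
      family = S4Vectors::mcols(feats)$ID[S4Vectors::subjectHits(ov)],
      stringsAsFactors = FALSE)
    df <- df[order(df$signature_id, df$family), ]
    df <- df[!duplicated(df$signature_id), ]
    df$family_class <- fc
    out[[fc]] <- df
  }
  if (length(out) == 0L)
    return(data.frame(signature_id = character(0), family = character(0),
                      family_class = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate per-library counts by family
#'
#' @param families data.frame from [assign_families()].
#' @param counts Integer matrix signatures x libraries.
#' @return A list with `counts` (matrix families x libraries) and
#'   `family_class` (named vector, `"MIRNA"`/`"TAS"` per family).
#' @export
family_counts <- function(families, counts) {
  fams <- sort(unique(families$family))
  libs <- colnames(counts)
  fm <- matrix(0L, nrow = length(fams), ncol = length(libs),
               dimnames = list(fams, libs))
  idx <- match(families$signature_id, rownames(counts))
  for (j in seq_along(libs)) {
    v <- tapply(counts[idx, j], families$family, sum)
    fm[names(v), j] <- as.integer(v)
  }
  cls <- families$family_class[match(fams, families$family)]
  list(counts = fm, family_class = stats::setNames(cls, fams))
}
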