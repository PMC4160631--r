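#' Collapse reads to unique signatures with per-library counts
#'
#' Applies the 17-30 nt length window, then collapses identical sequences
#' across all libraries into unique signatures. A singleton is a signature
#' with a total count of 1 across all libraries.
#'
#' @param reads_by_library Named list; one character vector of read sequences
#'   per library.
#' @param min_len,max_len Length window in nt (reads outside are removed and
#'   counted per library).
#' @return A list with `signatures` (data.frame `signature_id`, `sequence`,
#'   `length`, `total`), `counts` (integer matrix signatures x libraries),
#'   `removed_by_length` (named per-library counts), and `summary` (list with
#'   `n_unique`, `n_singleton`, `singleton_fraction`; the fraction is `NA`
#'   when there are no signatures).
#' @export
collapse_signatures <- function(reads_by_library, min_len = 17L, max_len = 30L) {
  stopifnot(is.list(reads_by_library), !is.null(names(reads_by_library)))
  libs <- names(reads_by_library)
  kept <- vector("list", length(libs))
  removed <- stats::setNames(integer(length(libs)), libs)
  for (i in seq_along(libs)) {
    r <- reads_by_library[[i]]
    len <- nchar(r)
    ok <- len >= min_len & len <= max_len
    removed[i] <- sum(!ok)
    kept[[i]] <- r[ok]
  }
  all_seqs <- sort(unique(unlist(kept, use.names = FALSE)))
  counts <- matrix(0L, nrow = length(all_seqs), ncol = length(libs),
                   dimnames = list(NULL, libs))
  for (i in seq_along(libs)) {
    tab <- table(kept[[i]])
    counts[match(names(tab), all_seqs), i] <- as.integer(tab)
  }
  total <- as.integer(rowSums(counts))
  # deterministic ids: most abundant first, ties broken by sequence
  o <- order(-total, all_seqs)
  all_seqs <- all_seqs[o]
  counts <- counts[o, , drop = FALSE]
  total <- total[o]
  ids <- sprintf("S%06d", seq_along(all_seqs))
  rownames(counts) <- ids
  n_singleton <- sum(total == 1L)
  list(signatures = data.frame(signature_id = ids, sequence = all_seqs,
                               length = nchar(all_seqs), total = total,
                               stringsAsFactors = FALSE),
       counts = counts,
       removed_by_length = removed,
       summary = list(n_unique = length(ids), n_singleton = n_singleton,
                      singleton_fraction = if (length(ids) > 0L)
                        n_singleton / length(ids) else NA_real_))
}

#' Map signature sequences exactly to a genome, both strands
#'
#' Reports every perfect-match occurrence of each sequence on the plus strand
#' and of its reverse complement (reported as a minus-strand hit at the
#' plus-strand coordinate of the reverse-complement match). A palindromic
#' sequence therefore yields a plus and a minus hit at the same start.
#' Sequences containing ambiguous bases are flagged invalid, never silently
#' dropped; sequences with zero hits are flagged unmapped.
#'
#' @param sequences Character vector of signature sequences; names are used
#'   as signature ids (default `S000001`...).
#' @param genome An `annotated_genome` or a [Biostrings::DNAStringSet].
#' @return A list with `hits` (a [GenomicRanges::GRanges], 1-based closed,
#'   with metadata column `signature_id`), `unmapped` (ids with no hit), and
#'   `invalid` (ids with non-ACGT characters).
#' @export
map_exact <- function(sequences, genome) {
  seqs <- if (inherits(genome, "annotated_genome")) genome$seqs else genome
  stopifnot(inherits(seqs, "DNAStringSet"))
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("S%06d", seq_along(sequences))
  ids <- names(sequences)
  valid <- grepl("^[ACGT]+$", sequences)
  invalid <- ids[!valid]
  vseq <- sequences[valid]
  vids <- ids[valid]
  chrom_names <- names(seqs)
  parts <- list()
  if (length(vseq) > 0L) {
    widths <- nchar(vseq)
    for (wd in sort(unique(widths))) {
      idx <- which(widths == wd)
      pats <- Biostrings::DNAStringSet(vseq[idx])
      pd_fwd <- Biostrings::PDict(pats)
      pd_rev <- Biostrings::PDict(Biostrings::reverseComplement(pats))
      for (ch in chrom_names) {
        subject <- seqs[[ch]]
        for (str in c("+", "-")) {
          pd <- if (str == "+") pd_fwd else pd_rev
          m <- Biostrings::matchPDict(pd, subject)
          starts <- Biostrings::startIndex(m)
          nhit <- lengths(starts)
          if (sum(nhit) == 0L) next
          parts[[length(parts) + 1L]] <- data.frame(
            chrom = ch,
            start = unlist(starts, use.names = FALSE),
            width = wd,
            strand = str,
            signature_id = rep(vids[idx], nhit),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(parts) > 0L) {
    tab <- do.call(rbind, parts)
    hits <- GenomicRanges::GRanges(
      seqnames = tab$chrom,
      ranges = IRanges::IRanges(start = tab$start, width = tab$width),
      strand = tab$strand)
    S4Vectors::mcols(hits)$signature_id <- tab$signature_id
    hits <- GenomicRanges::sort(hits, ignore.strand = TRUE)
    hit_ids <- unique(tab$signature_id)
  } else {
    hits <- GenomicRanges::GRanges()
    S4Vectors::mcols(hits)$signature_id <- character(0)
    hit_ids <- character(0)
  }
  GenomeInfoDb::seqlevels(hits) <- chrom_names
  GenomeInfoDb::seqlengths(hits) <-
    stats::setNames(Biostrings::width(seqs), chrom_names)
  list(hits = hits, unmapped = setdiff(vids, hit_ids), invalid = invalid)
}

#' Eliminate signatures hitting structural RNA loci
#'
#' A signature is removed if any of its hits overlaps (by at least 1 nt, on
#' either strand) a tRNA, rRNA, snoRNA or snRNA feature; all other signatures
#' are retained. The conservative any-hit rule prevents structural-RNA
#' fragments from leaking into downstream categories.
#'
#' @param hits `GRanges` of mapped hits with a `signature_id` column.
#' @param annotation `GRanges` of features with a `type` column.
#' @param signature_ids Optional full set of signature ids expected to be
#'   mapped; ids without any hit trigger an error (map first).
#' @return A list with `hits` (retained hits), `removed` (removed signature
#'   ids, sorted) and `retained` (retained ids).
#' @export
filter_structural <- function(hits, annotation, signature_ids = NULL) {
  stopifnot(inherits(hits, "GRanges"),
            "signature_id" %in% colnames(S4Vectors::mcols(hits)),
            inherits(annotation, "GRanges"),
            "type" %in% colnames(S4Vectors::mcols(annotation)))
  sig_in_hits <- unique(S4Vectors::mcols(hits)$signature_id)
  if (!is.null(signature_ids)) {
    missing <- setdiff(signature_ids, sig_in_hits)
    if (length(missing) > 0L)
      stop("unmapped signature(s) encountered (map first): ",
           paste(utils::head(missing, 5L), collapse = ", "))
  }
  structural <- annotation[S4Vectors::mcols(annotation)$type %in%
                             structural_categories()]
  if (length(structural) == 0L)
    return(list(hits = hits, removed = character(0), retained = sig_in_hits))
  ov <- GenomicRanges::findOverlaps(hits, structural, ignore.strand = TRUE)
  removed <- sort(unique(
    S4Vectors::mcols(hits)$signature_id[S4Vectors::queryHits(ov)]))
  keep <- !(S4Vectors::mcols(hits)$signature_id %in% removed)
  list(hits = hits[keep], removed = removed,
       retained = setdiff(sig_in_hits, removed))
}
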