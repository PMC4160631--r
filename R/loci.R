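#' Group mapped hits into small-RNA loci under the <150 nt gap rule
#'
#' Single-linkage, strand-agnostic merge per chromosome: two hit intervals
#' belong to the same locus when the gap between them (bases strictly between
#' the nearer ends) is less than `gap` nt. A gap of exactly `gap` keeps the
#' intervals in separate loci. Overlapping and bookended intervals always
#' merge.
#'
#' @param hits `GRanges` of mapped hits with a `signature_id` column.
#' @param gap Gap threshold in nt (default 150).
#' @return `GRanges` of disjoint, sorted loci with metadata columns
#'   `locus_id`, `n_members` (number of member hits) and `members`
#'   (a [IRanges::CharacterList] of member signature ids, unique per locus).
#' @export
cluster_loci <- function(hits, gap = 150L) {
  stopifnot(inherits(hits, "GRanges"), gap >= 1L)
  if (length(hits) > 0L && min(GenomicRanges::start(hits)) < 1L)
    stop("negative or zero coordinates in hits")
  sig <- S4Vectors::mcols(hits)$signature_id
  if (is.null(sig)) sig <- rep(NA_character_, length(hits))
  red <- GenomicRanges::reduce(GenomicRanges::granges(hits),
                               min.gapwidth = gap,
                               ignore.strand = TRUE, with.revmap = TRUE)
  red <- GenomicRanges::sort(red, ignore.strand = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  members <- IRanges::CharacterList(lapply(revmap, function(ix)
    sort(unique(sig[ix]))))
  out <- GenomicRanges::granges(red)
  S4Vectors::mcols(out)$locus_id <- sprintf("L%05d", seq_along(out))
  S4Vectors::mcols(out)$n_members <- lengths(revmap)
  S4Vectors::mcols(out)$members <- members
  out
}

#' Per-library locus counts
#'
#' Reproduces the "number of loci" summary statistic: for each library, the
#' loci formed by the hits of signatures observed (count > 0) in that
#' library.
#'
#' @param hits `GRanges` of mapped hits with `signature_id`.
#' @param counts Integer matrix signatures x libraries (rownames are
#'   signature ids).
#' @param gap Gap threshold in nt.
#' @return Named integer vector of locus counts per library.
#' @export
count_library_loci <- function(hits, counts, gap = 150L) {
  libs <- colnames(counts)
  sig <- S4Vectors::mcols(hits)$signature_id
  vapply(libs, function(lib) {
    present <- rownames(counts)[counts[, lib] > 0L]
    length(cluster_loci(hits[sig %in% present], gap = gap))
  }, integer(1))
}

#' Export loci to BED (0-based half-open)
#'
#' Internal coordinates are 1-based closed; BED output converts at the
#' boundary, so a locus covering bases 101..120 is written as `100\t120`.
#'
#' @param loci `GRanges` of loci (from [cluster_loci()]).
#' @param path Output file path.
#' @export
write_loci_bed <- function(loci, path) {
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(loci)),
                   start = GenomicRanges::start(loci) - 1L,
                   end = GenomicRanges::end(loci),
                   name = S4Vectors::mcols(loci)$locus_id,
                   score = S4Vectors::mcols(loci)$n_members,
                   strand = ".",
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read loci from BED
#' @param path BED file path.
#' @return `GRanges` (1-based closed internally).
#' @export
read_loci_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(
    seqnames = df[[1]],
    ranges = IRanges::IRanges(start = df[[2]] + 1L, end = df[[3]]))
  if (ncol(df) >= 4L) S4Vectors::mcols(gr)$locus_id <- df[[4]]
  if (ncol(df) >= 5L) S4Vectors::mcols(gr)$n_members <- df[[5]]
  gr
}
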