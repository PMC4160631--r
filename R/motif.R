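#' Scan promoters for a cis-element
#'
#' Extracts up to `window` nt upstream of each protein-coding gene's start on
#' the gene's strand (truncated at the chromosome edge) and searches,
#' case-insensitively, for the motif and its reverse complement (auxin
#' response elements are functional on either strand; set
#' `both_strands = FALSE` for the sense-only reading). Offsets are 0-based
#' from the 5'-most base of the oriented window, matching
#' [plant_promoter_motifs()].
#'
#' @param genome An `annotated_genome`, or a [Biostrings::DNAStringSet] with
#'   `annotation` supplied.
#' @param annotation Feature `GRanges` (defaults to the genome's features);
#'   genes lacking a strand (`*`) raise an error.
#' @param motif Motif over ACGT (default `"TGTCTC"`, the AuxRE core).
#' @param window Upstream window length in nt (default 1000).
#' @param both_strands Search the reverse complement too (default TRUE).
#' @return A list with `hits` (data.frame `gene_id`, `offset`, `orientation`
#'   = `"sense"`/`"antisense"`) and `gene_summary` (data.frame `gene_id`,
#'   `has_motif`).
#' @export
scan_promoter_motif <- function(genome, annotation = NULL, motif = "TGTCTC",
                                window = 1000L, both_strands = TRUE) {
  if (inherits(genome, "annotated_genome")) {
    seqs <- genome$seqs
    if (is.null(annotation)) annotation <- genome$features
  } else seqs <- genome
  stopifnot(inherits(seqs, "DNAStringSet"), !is.null(annotation),
            grepl("^[ACGTacgt]+$", motif))
  motif <- toupper(motif)
  m <- nchar(motif)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  genes <- annotation[S4Vectors::mcols(annotation)$type == "protein_coding_gene"]
  strands <- as.character(BiocGenerics::strand(genes))
  if (any(strands == "*"))
    stop("gene(s) lacking strand: ",
         paste(S4Vectors::mcols(genes)$ID[strands == "*"], collapse = ", "))
  hits <- list()
  has <- logical(length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    ch <- as.character(GenomeInfoDb::seqnames(g))
    chrom_len <- Biostrings::width(seqs)[match(ch, names(seqs))]
    if (strands[i] == "+") {
      ws <- max(1L, GenomicRanges::start(g) - window)
      we <- GenomicRanges::start(g) - 1L
    } else {
      ws <- GenomicRanges::end(g) + 1L
      we <- min(chrom_len, GenomicRanges::end(g) + window)
    }
    if (we < ws || we - ws + 1L < m) next
    prom <- toupper(.strand_seq(seqs, ch, ws, we, strands[i]))
    find_all <- function(pat) {
      out <- integer(0)
      from <- 1L
      repeat {
        p <- regexpr(pat, substr(prom, from, nchar(prom)), fixed = TRUE)
        if (p < 0) break
        out <- c(out, from + as.integer(p) - 1L)
        from <- from + as.integer(p)
      }
      out
    }
    sense <- find_all(motif)
    anti <- if (both_strands && rc != motif) find_all(rc) else integer(0)
    if (length(sense) + length(anti) > 0L) {
      has[i] <- TRUE
      hits[[length(hits) + 1L]] <- data.frame(
        gene_id = S4Vectors::mcols(g)$ID,
        offset = c(sense, anti) - 1L,
        orientation = c(rep("sense", length(sense)),
                        rep("antisense", length(anti))),
        stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(hits) > 0L) do.call(rbind, hits) else
    data.frame(gene_id = character(0), offset = integer(0),
               orientation = character(0))
  hits <- hits[order(hits$gene_id, hits$offset), , drop = FALSE]
  rownames(hits) <- NULL
  list(hits = hits,
       gene_summary = data.frame(gene_id = S4Vectors::mcols(genes)$ID,
                                 has_motif = has, stringsAsFactors = FALSE))
}
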