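#' Feature categories of the annotated toy genome
#'
#' Category vocabulary used in the `type` column of the feature table and of
#' exported GFF3. The first six categories drive read classification; the
#' last four are structural RNAs that the small-RNA pipeline eliminates.
#'
#' @return Character vector of category names.
#' @export
feature_categories <- function() {
  c("protein_coding_gene", "TE_gene", "pseudogene", "intergenic_TE",
    "MIRNA", "TAS", "tRNA", "rRNA", "snoRNA", "snRNA")
}

structural_categories <- function() c("tRNA", "rRNA", "snoRNA", "snRNA")

# length range (nt) drawn uniformly per feature of each category
.category_length_ranges <- list(
  protein_coding_gene = c(1000L, 3000L),
  TE_gene             = c(500L, 2000L),
  pseudogene          = c(400L, 1200L),
  intergenic_TE       = c(200L, 800L),
  MIRNA               = c(100L, 150L),
  TAS                 = c(500L, 900L),
  tRNA                = c(70L, 90L),
  rRNA                = c(120L, 200L),
  snoRNA              = c(70L, 150L),
  snRNA               = c(100L, 200L)
)

#' Specification of a synthetic annotated genome
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Length of each chromosome in nt.
#' @param n_features Named integer vector giving the number of features to
#'   place per category; names must be a subset of [feature_categories()].
#' @param margin Minimum clearance (nt) kept between features and from the
#'   chromosome ends. The default of 1100 nt guarantees every protein-coding
#'   gene an unobstructed 1 kb promoter window and keeps distinct features
#'   from merging under the 150 nt locus gap rule.
#' @param seed Integer seed; the generated genome is a pure function of the
#'   spec including this seed.
#'
#' @return A list of class `genome_spec`.
#' @export
genome_spec <- function(n_chromosomes = 2L,
                        chrom_length = 200000L,
                        n_features = c(protein_coding_gene = 20L, TE_gene = 8L,
                                       pseudogene = 6L, intergenic_TE = 10L,
                                       MIRNA = 8L, TAS = 3L, tRNA = 4L,
                                       rRNA = 4L, snoRNA = 4L, snRNA = 4L),
                        margin = 1100L,
                        seed = 1L) {
  stopifnot(n_chromosomes >= 1L, chrom_length >= 1000L, margin >= 0L)
  if (length(n_features) > 0L) {
    bad <- setdiff(names(n_features), feature_categories())
    if (length(bad) > 0L)
      stop("unknown feature categories: ", paste(bad, collapse = ", "))
    stopifnot(all(n_features >= 0L))
  }
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chrom_length = as.integer(chrom_length),
                 n_features = n_features,
                 margin = as.integer(margin),
                 seed = as.integer(seed)),
            class = "genome_spec")
}

.id_prefix <- c(protein_coding_gene = "PC", TE_gene = "TE", pseudogene = "PS",
                intergenic_TE = "ITE", MIRNA = "MIR", TAS = "TAS",
                tRNA = "TRNA", rRNA = "RRNA", snoRNA = "SNO", snRNA = "SNR")

#' Generate an annotated toy genome
#'
#' Draws uniform-random chromosome sequences and places non-overlapping typed
#' features by rejection sampling. Every MIRNA locus stores the genomic start
#' of one 21 nt mature sequence; every TAS locus stores a phase-start
#' coordinate from which 21 nt phased siRNAs are emitted in register.
#'
#' @param spec A [genome_spec()].
#' @return An object of class `annotated_genome`: a list with elements
#'   `seqs` (a [Biostrings::DNAStringSet] of chromosomes) and `features`
#'   (a [GenomicRanges::GRanges] with metadata columns `ID`, `type`, and,
#'   for MIRNA/TAS loci, `mature_start` / `phase_start`).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(spec$seed)
  chrom_names <- paste0("chr", seq_len(spec$n_chromosomes))
  seqs <- Biostrings::DNAStringSet(vapply(chrom_names, function(ch) {
    paste(sample(c("A", "C", "G", "T"), spec$chrom_length, replace = TRUE),
          collapse = "")
  }, character(1)))
  names(seqs) <- chrom_names

  nf <- spec$n_features
  nf <- nf[nf > 0L]
  occupied <- lapply(chrom_names, function(ch) IRanges::IRanges())
  names(occupied) <- chrom_names
  rows <- list()
  counter <- 0L
  for (cat in names(nf)) {
    rng <- .category_length_ranges[[cat]]
    for (i in seq_len(nf[[cat]])) {
      placed <- FALSE
      for (try in seq_len(500L)) {
        len <- sample(seq.int(rng[1], rng[2]), 1L)
        ch <- sample(chrom_names, 1L)
        lo <- spec$margin + 1L
        hi <- spec$chrom_length - len - spec$margin + 1L
        if (hi < lo) next
        start <- sample(seq.int(lo, hi), 1L)
        cand <- IRanges::IRanges(start = start, width = len)
        grown <- IRanges::IRanges(start = start - spec$margin,
                                  width = len + 2L * spec$margin)
        if (length(IRanges::findOverlaps(grown, occupied[[ch]])) == 0L) {
          occupied[[ch]] <- c(occupied[[ch]], cand)
          counter <- counter + 1L
          rows[[counter]] <- data.frame(
            chrom = ch, start = start, end = start + len - 1L,
            strand = sample(c("+", "-"), 1L),
            type = cat,
            ID = sprintf("%s%04d", .id_prefix[[cat]], i),
            stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place feature of category '", cat,
             "' after 500 tries; chromosome too crowded")
    }
  }

  if (counter == 0L) {
    features <- GenomicRanges::GRanges(seqnames = character(0),
                                       ranges = IRanges::IRanges())
    S4Vectors::mcols(features)$ID <- character(0)
    S4Vectors::mcols(features)$type <- character(0)
    S4Vectors::mcols(features)$mature_start <- integer(0)
    S4Vectors::mcols(features)$phase_start <- integer(0)
  } else {
    tab <- do.call(rbind, rows)
    features <- GenomicRanges::GRanges(
      seqnames = tab$chrom,
      ranges = IRanges::IRanges(start = tab$start, end = tab$end),
      strand = tab$strand)
    S4Vectors::mcols(features)$ID <- tab$ID
    S4Vectors::mcols(features)$type <- tab$type
    mature <- rep(NA_integer_, counter)
    phase <- rep(NA_integer_, counter)
    is_mir <- tab$type == "MIRNA"
    if (any(is_mir))
      mature[is_mir] <- tab$start[is_mir] +
        vapply(tab$end[is_mir] - tab$start[is_mir] + 1L - 21L,
               function(room) sample(seq.int(0L, room), 1L), integer(1))
    is_tas <- tab$type == "TAS"
    if (any(is_tas))
      phase[is_tas] <- tab$start[is_tas] +
        vapply(rep(20L, sum(is_tas)),
               function(room) sample(seq.int(0L, room), 1L), integer(1))
    S4Vectors::mcols(features)$mature_start <- mature
    S4Vectors::mcols(features)$phase_start <- phase
    o <- order(tab$chrom, tab$start)
    features <- features[o]
  }
  GenomeInfoDb::seqlevels(features) <- chrom_names
  GenomeInfoDb::seqlengths(features) <-
    stats::setNames(rep(spec$chrom_length, spec$n_chromosomes), chrom_names)
  structure(list(seqs = seqs, features = features), class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat("annotated_genome:", length(x$seqs), "chromosome(s),",
      sum(Biostrings::width(x$seqs)), "nt,",
      length(x$features), "feature(s)\n")
  if (length(x$features) > 0L)
    print(table(S4Vectors::mcols(x$features)$type))
  invisible(x)
}

# genomic subsequence on a given strand (reverse-complemented for "-")
.strand_seq <- function(seqs, chrom, start, end, strand) {
  s <- Biostrings::subseq(seqs[[chrom]], start = start, end = end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Plant a promoter motif upstream of protein-coding genes
#'
#' For a Bernoulli(`rate`) subset of protein-coding genes the motif is written
#' into the genome within the 1 kb window upstream of the gene start, on the
#' gene's strand. Offsets are 0-based distances from the 5'-most base of the
#' oriented upstream window (the base farthest from the gene), matching the
#' coordinates reported by [scan_promoter_motif()].
#'
#' @param genome An `annotated_genome`.
#' @param rate Planting probability per gene, in \[0, 1\].
#' @param motif Motif over ACGT (default the auxin response element TGTCTC).
#' @param window Upstream window length in nt.
#' @param seed Integer seed.
#' @return A list with `genome` (modified copy) and `truth`, a data.frame of
#'   planted positions (`gene_id`, `offset`, `genomic_start`, `strand`), plus
#'   `skipped`: gene ids whose upstream window was shorter than the motif.
#' @export
plant_promoter_motifs <- function(genome, rate, motif = "TGTCTC",
                                  window = 1000L, seed = 1L) {
  stopifnot(inherits(genome, "annotated_genome"),
            rate >= 0, rate <= 1, grepl("^[ACGTacgt]+$", motif))
  motif <- toupper(motif)
  m <- nchar(motif)
  set.seed(seed)
  feats <- genome$features
  genes <- feats[S4Vectors::mcols(feats)$type == "protein_coding_gene"]
  truth <- list()
  skipped <- character(0)
  chars <- as.list(lapply(genome$seqs, as.character))
  for (i in seq_along(genes)) {
    g <- genes[i]
    ch <- as.character(GenomeInfoDb::seqnames(g))
    chrom_len <- nchar(chars[[ch]])
    if (as.character(BiocGenerics::strand(g)) == "+") {
      win_start <- max(1L, GenomicRanges::start(g) - window)
      win_end <- GenomicRanges::start(g) - 1L
    } else {
      win_start <- GenomicRanges::end(g) + 1L
      win_end <- min(chrom_len, GenomicRanges::end(g) + window)
    }
    win_len <- win_end - win_start + 1L
    if (win_len < m) {
      skipped <- c(skipped, S4Vectors::mcols(g)$ID)
      next
    }
    if (stats::runif(1) >= rate) next
    offset <- sample(seq.int(0L, win_len - m), 1L)
    # offset counts from the window's 5' end in gene orientation
    if (as.character(BiocGenerics::strand(g)) == "+") {
      gpos <- win_start + offset
      written <- motif
    } else {
      gpos <- win_end - offset - m + 1L
      written <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(motif)))
    }
    substr(chars[[ch]], gpos, gpos + m - 1L) <- written
    truth[[length(truth) + 1L]] <- data.frame(
      gene_id = S4Vectors::mcols(g)$ID, offset = offset,
      genomic_start = gpos,
      strand = as.character(BiocGenerics::strand(g)),
      stringsAsFactors = FALSE)
  }
  truth <- if (length(truth) > 0L) do.call(rbind, truth) else
    data.frame(gene_id = character(0), offset = integer(0),
               genomic_start = integer(0), strand = character(0))
  out <- genome
  out$seqs <- Biostrings::DNAStringSet(unlist(chars))
  names(out$seqs) <- names(genome$seqs)
  # a later planting can clobber an earlier one when upstream windows of two
  # genes overlap; keep only motifs still intact in the final sequence
  if (nrow(truth) > 0L) {
    intact <- vapply(seq_len(nrow(truth)), function(j) {
      ch <- truth$strand[j]
      g <- genes[match(truth$gene_id[j], S4Vectors::mcols(genes)$ID)]
      chn <- as.character(GenomeInfoDb::seqnames(g))
      got <- substr(chars[[chn]], truth$genomic_start[j],
                    truth$genomic_start[j] + m - 1L)
      expected <- if (ch == "+") motif else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
      identical(got, expected)
    }, logical(1))
    if (!all(intact))
      warning(sum(!intact), " planted motif(s) overwritten by later plantings")
    truth <- truth[intact, , drop = FALSE]
    rownames(truth) <- NULL
  }
  list(genome = out, truth = truth, skipped = skipped)
}

#' Write genome chromosomes to FASTA
#' @param genome An `annotated_genome`.
#' @param path Output file path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome$seqs, filepath = path)
  invisible(path)
}

#' Read genome chromosomes from FASTA
#' @param path FASTA file path.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write the feature table to GFF3 (1-based closed intervals)
#' @param genome An `annotated_genome` or a `GRanges` of features.
#' @param path Output file path.
#' @export
write_annotation_gff3 <- function(genome, path) {
  feats <- if (inherits(genome, "annotated_genome")) genome$features else genome
  rtracklayer::export.gff3(feats, path)
  invisible(path)
}

#' Read a feature table from GFF3
#' @param path GFF3 file path.
#' @return A [GenomicRanges::GRanges] with `ID` and `type` metadata columns.
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import.gff3(path)
  mc <- S4Vectors::mcols(gr)
  keep <- intersect(c("ID", "type", "mature_start", "phase_start"),
                    colnames(mc))
  S4Vectors::mcols(gr) <- mc[, keep, drop = FALSE]
  if ("type" %in% keep)
    S4Vectors::mcols(gr)$type <- as.character(S4Vectors::mcols(gr)$type)
  for (col in intersect(c("mature_start", "phase_start"), keep))
    S4Vectors::mcols(gr)[[col]] <- as.integer(S4Vectors::mcols(gr)[[col]])
  gr
}
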