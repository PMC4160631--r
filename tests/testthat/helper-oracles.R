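# Independent brute-force oracles used to cross-check the implementation.

# naive both-strand substring scan; returns data.frame(chrom, start, strand),
# 1-based starts on the plus strand
naive_map <- function(sequence, seqs) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(sequence)))
  out <- list()
  for (ch in names(seqs)) {
    subject <- as.character(seqs[[ch]])
    for (str in c("+", "-")) {
      pat <- if (str == "+") sequence else rc
      n <- nchar(subject) - nchar(pat) + 1L
      if (n < 1L) next
      starts <- which(vapply(seq_len(n), function(i)
        substr(subject, i, i + nchar(pat) - 1L) == pat, logical(1)))
      if (length(starts) > 0L)
        out[[length(out) + 1L]] <- data.frame(chrom = ch, start = starts,
                                              strand = str,
                                              stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      strand = character(0)))
  df <- do.call(rbind, out)
  df[order(df$chrom, df$start, df$strand), , drop = FALSE]
}

# transitive closure of the pairwise gap<gap relation on 1-based closed
# intervals; returns a data.frame of merged intervals sorted by start
brute_force_loci <- function(starts, ends, gap = 150L) {
  n <- length(starts)
  if (n == 0L) return(data.frame(start = integer(0), end = integer(0)))
  related <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    g <- max(starts[i], starts[j]) - min(ends[i], ends[j]) - 1L
    related[i, j] <- g < gap
  }
  # transitive closure
  repeat {
    nxt <- related | (related %*% related > 0)
    if (identical(nxt, related)) break
    related <- nxt
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) if (is.na(comp[i])) {
    cid <- cid + 1L
    comp[related[i, ]] <- cid
  }
  agg <- data.frame(
    start = tapply(starts, comp, min),
    end = tapply(ends, comp, max))
  agg[order(agg$start), , drop = FALSE]
}

# exhaustive enumeration of hypergeometric tails for N <= 12
enumerate_hyper <- function(k, n, K, N) {
  pop <- c(rep(1L, K), rep(0L, N - K))
  draws <- utils::combn(N, n)
  succ <- apply(draws, 2L, function(ix) sum(pop[ix]))
  c(p_up = mean(succ >= k), p_down = mean(succ <= k))
}

# naive promoter motif scan over both orientations; 0-based offsets in the
# oriented promoter string
naive_motif_positions <- function(promoter, motif) {
  promoter <- toupper(promoter)
  motif <- toupper(motif)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(motif)))
  hit_at <- function(pat) {
    n <- nchar(promoter) - nchar(pat) + 1L
    if (n < 1L) return(integer(0))
    which(vapply(seq_len(n), function(i)
      substr(promoter, i, i + nchar(pat) - 1L) == pat, logical(1))) - 1L
  }
  pats <- unique(c(motif, rc))
  ori <- c("sense", "antisense")[seq_along(pats)]
  do.call(rbind, lapply(seq_along(pats), function(j) {
    pos <- hit_at(pats[j])
    data.frame(offset = pos, orientation = rep(ori[j], length(pos)),
               stringsAsFactors = FALSE)
  }))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
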