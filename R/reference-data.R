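#' Published per-library summary of the reference smRNA-seq dataset
#'
#' The seven-library 454 small-RNA dataset whose analysis this package
#' mirrors reported, per treatment library, the number of genome-mapped
#' sequences after structural-RNA elimination and the number of <150 nt-gap
#' loci. These printed counts serve as arithmetic consistency inputs: the
#' per-library sequence counts must sum to the reported dataset-level total
#' (see [reference_signature_summary()]).
#'
#' @return data.frame with `library`, `n_sequences`, `n_loci`.
#' @export
reference_library_summary <- function() {
  read_tsv_table(system.file("extdata", "reference_library_summary.tsv",
                             package = "stressSmallRNA", mustWork = TRUE))
}

#' Published dataset-level signature statistics of the reference dataset
#'
#' Total raw reads, genome-mapped sequences, unique signatures over all
#' seven libraries, and singleton signatures (represented by a single read).
#'
#' @return Named numeric vector.
#' @export
reference_signature_summary <- function() {
  df <- read_tsv_table(system.file("extdata", "reference_signature_summary.tsv",
                                   package = "stressSmallRNA", mustWork = TRUE))
  stats::setNames(df$value, df$statistic)
}
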