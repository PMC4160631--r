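#' Write a data.frame as TSV
#' @param df data.frame.
#' @param path Output file path.
#' @export
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_table()]
#' @param path File path.
#' @return data.frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write per-library reads as sequence + count TSV
#' @param reads_by_library Named list of read-sequence character vectors.
#' @param path Output file path.
#' @export
write_reads_tsv <- function(reads_by_library, path) {
  rows <- lapply(names(reads_by_library), function(lib) {
    tab <- table(reads_by_library[[lib]])
    if (length(tab) == 0L)
      return(data.frame(library = character(0), sequence = character(0),
                        count = integer(0)))
    data.frame(library = lib, sequence = names(tab),
               count = as.integer(tab), stringsAsFactors = FALSE)
  })
  write_tsv_table(do.call(rbind, rows), path)
}

#' Read per-library reads from a sequence + count TSV
#' @param path File path.
#' @return Named list of read-sequence character vectors (counts expanded).
#' @export
read_reads_tsv <- function(path) {
  df <- read_tsv_table(path)
  stopifnot(all(c("library", "sequence", "count") %in% colnames(df)))
  lapply(split(df, df$library), function(d) rep(d$sequence, d$count))
}

#' Write GO gene sets as term/gene pairs TSV
#' @param memberships data.frame `term`, `gene_id`.
#' @param path Output file path.
#' @export
write_go_tsv <- function(memberships, path) {
  write_tsv_table(memberships[, c("term", "gene_id")], path)
}

#' Read GO gene sets from a term/gene pairs TSV
#' @param path File path.
#' @return Named list of gene-id vectors, one per term.
#' @export
read_go_tsv <- function(path) {
  df <- read_tsv_table(path)
  stopifnot(all(c("term", "gene_id") %in% colnames(df)))
  lapply(split(df$gene_id, df$term), unname)
}

#' Write an expression matrix with its sample-annotation sidecar
#' @param fm A `factorial_matrix`.
#' @param path Matrix TSV path; the sample sheet goes to
#'   `<path>.samples.tsv`.
#' @export
write_expression_tsv <- function(fm, path) {
  df <- data.frame(gene_id = rownames(fm$exprs), fm$exprs,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_table(df, path)
  write_tsv_table(fm$samples, paste0(path, ".samples.tsv"))
  invisible(path)
}

#' Read an expression matrix with its sample-annotation sidecar
#' @param path Matrix TSV path (expects `<path>.samples.tsv` beside it).
#' @return A `factorial_matrix` (without simulation truth).
#' @export
read_expression_tsv <- function(path) {
  df <- read_tsv_table(path)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  samples <- read_tsv_table(paste0(path, ".samples.tsv"))
  structure(list(exprs = mat, samples = samples,
                 go_memberships = data.frame(term = character(0),
                                             gene_id = character(0)),
                 truth = NULL),
            class = "factorial_matrix")
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults of
#' [default_pipeline_config()]; thresholds are validated.
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_lists <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]]) &&
          !is.null(names(over[[nm]])))
        base[[nm]] <- merge_lists(base[[nm]], over[[nm]])
      else base[[nm]] <- over[[nm]]
    }
    base
  }
  cfg <- merge_lists(default_pipeline_config(), user)
  validate_pipeline_config(cfg)
  cfg
}

#' Write a pipeline configuration to YAML
#' @param config Configuration list.
#' @param path Output path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
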