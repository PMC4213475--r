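#' Read a feature x sample expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of feature
#' (probe or gene) ids.
#'
#' @param path TSV file.
#' @return Numeric matrix with feature rownames and sample colnames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression TSV needs an id column plus samples")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  rownames(m) <- as.character(df[[1]])
  if (anyDuplicated(rownames(m))) stop("duplicated feature ids in ", path)
  m
}

#' Read a probe-to-gene map from TSV
#'
#' @param path TSV with columns `probe_id`, `gene_id`.
#' @return Data frame with those two character columns.
#' @export
read_probe_map_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "gene_id") %in% names(df)))
    stop("probe map TSV must have columns probe_id, gene_id")
  df$probe_id <- as.character(df$probe_id)
  df$gene_id <- as.character(df$gene_id)
  df
}

#' Read a sample design (sample, group) from TSV
#'
#' @param path TSV with columns `sample`, `group` (two distinct groups).
#' @return Named factor: sample -> group.
#' @export
read_design_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(df)))
    stop("design TSV must have columns sample, group")
  stats::setNames(factor(df$group), as.character(df$sample))
}

#' Write a numeric matrix as TSV
#'
#' Values are written with 6 significant digits (stable golden files).
#'
#' @param m Matrix with rownames/colnames.
#' @param path Output file.
#' @param id_col Name for the row-id column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), signif(m, 6), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write circuit test results as TSV
#'
#' @param results A `circuit_results` data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(results, path) {
  df <- as.data.frame(results)
  for (col in c("p_value", "fdr_p", "location"))
    df[[col]] <- signif(df[[col]], 6)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
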