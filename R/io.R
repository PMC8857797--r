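# Plain-text readers/writers shared by the pipeline stages. All writers
# are deterministic (fixed column order, no row names) so that repeated
# runs with the same inputs produce byte-identical files.

#' Write a data.frame as TSV (deterministic, no row names)
#' @param x Data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path Input path.
#' @return A data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write a count matrix as TSV with feature ids in the first column
#' @param mat Feature-by-sample matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_count_matrix <- function(mat, path) {
  df <- data.frame(feature_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a count matrix written by [write_count_matrix()]
#' @param path Input path.
#' @return Feature-by-sample numeric matrix.
#' @export
read_count_matrix <- function(path) {
  df <- read_tsv(path)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}
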