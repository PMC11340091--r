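# Plain-text readers/writers for the pipeline's file formats.

#' Read a miRNA count matrix from TSV
#'
#' Expects a tab-separated file whose first column holds miRNA ids and
#' whose remaining columns hold integer counts per sample.
#'
#' @param path file path.
#' @return Integer matrix, miRNAs x samples.
#' @export
read_counts <- function(path) {
  d <- read.csv(path, sep = "\t", check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "numeric"
  check_count_matrix(m)
  m
}

#' Write a miRNA count matrix to TSV
#'
#' @param counts matrix, miRNAs x samples.
#' @param path output path.
#' @export
write_counts <- function(counts, path) {
  d <- data.frame(mirna_id = rownames(counts), counts, check.names = FALSE,
                  stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a normalized/transformed expression matrix to TSV
#'
#' @param expr numeric matrix, miRNAs x samples.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  d <- data.frame(mirna_id = rownames(expr),
                  apply(expr, 2, function(x) sprintf("%.6g", x)),
                  check.names = FALSE, stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a clinical + outcome table from CSV
#'
#' Expects columns `patient_id,age,sex,stage,dfs_months,dfs_event` (extra
#' columns are kept).
#'
#' @param path file path.
#' @return A data frame.
#' @export
read_clinical <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "age", "sex", "stage", "dfs_months", "dfs_event")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("clinical table is missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(d$patient_id)) stop("duplicated patient_id in clinical table")
  d
}
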