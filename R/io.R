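# TSV I/O for count/expression matrices and sample tables.

#' Read a wide counts/expression TSV
#'
#' First column is the gene id (renamed `gene_id` whatever its header),
#' remaining columns one per sample.
#'
#' @param file TSV path.
#' @return Wide tibble with `gene_id` + numeric sample columns.
#' @export
read_counts <- function(file) {
  tbl <- readr::read_tsv(file, show_col_types = FALSE)
  names(tbl)[1] <- "gene_id"
  tbl$gene_id <- as.character(tbl$gene_id)
  tbl
}

#' Read a sample table TSV
#'
#' @param file TSV path with a header including `sample_id` and `diagnosis`.
#' @return Tibble.
#' @export
read_sample_table <- function(file) {
  tbl <- readr::read_tsv(file, show_col_types = FALSE)
  need <- setdiff(c("sample_id", "diagnosis"), names(tbl))
  if (length(need)) {
    abort(sprintf("sample table misses column(s): %s", paste(need, collapse = ", ")))
  }
  if (anyNA(tbl$diagnosis)) abort("diagnosis must be non-missing for every sample")
  if (anyDuplicated(tbl$sample_id)) abort("sample_id values must be unique")
  tbl
}

#' Write a wide tibble as TSV
#'
#' @param tbl Tibble.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_tsv_quiet <- function(tbl, file) {
  readr::write_tsv(tbl, file)
  invisible(file)
}
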