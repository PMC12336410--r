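# Internal helpers shared across modules.

#' @importFrom rlang abort warn inform %||% .data
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join bind_rows distinct rename across all_of n pull
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats median mad sd var quantile pt p.adjust fisher.test
#'   rnorm rnbinom runif setNames complete.cases lm coef
NULL

# Convert a wide expression/count tibble (gene_id + one column per sample)
# to a numeric matrix with gene_id rownames.
wide_to_matrix <- function(tbl, id_col = "gene_id") {
  if (!is.data.frame(tbl)) abort("expected a data frame")
  if (!id_col %in% names(tbl)) {
    abort(sprintf("column '%s' is required as the first (gene id) column", id_col))
  }
  ids <- as.character(tbl[[id_col]])
  if (anyDuplicated(ids)) abort("gene ids must be unique")
  m <- as.matrix(tbl[setdiff(names(tbl), id_col)])
  if (is.logical(m)) storage.mode(m) <- "double"
  if (!is.numeric(m)) abort("all sample columns must be numeric")
  rownames(m) <- ids
  m
}

matrix_to_wide <- function(m, id_col = "gene_id") {
  out <- as_tibble(m, .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble(!!id_col := rownames(m)), out)
  out
}

sample_cols <- function(tbl, id_col = "gene_id") setdiff(names(tbl), id_col)

# Deterministic RNG scoping: run `code` under `seed` without touching the
# caller's RNG stream.
with_fixed_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

check_samples_match <- function(tbl_a, tbl_b, what = c("exonic", "intronic")) {
  sa <- sample_cols(tbl_a)
  sb <- sample_cols(tbl_b)
  if (!identical(sa, sb)) {
    abort(sprintf("%s and %s matrices must share identical sample columns",
                  what[1], what[2]))
  }
  invisible(sa)
}
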