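# counts_prep: TPM expression filter, TMM normalization, log2 CPM, and
# covariate residualization. Exonic and intronic matrices are processed
# independently end-to-end; the expressed-gene filter is computed on exonic
# TPM only and the surviving gene set applied to both.

#' Transcripts per million from exonic counts
#'
#' Per sample, `TPM_g = (count_g / length_g) / sum_h(count_h / length_h) * 1e6`,
#' so columns with any signal sum to one million. Gene lengths are the
#' composite exon lengths from [build_annotation()].
#'
#' @param counts Wide count tibble: `gene_id` column plus one numeric column
#'   per sample.
#' @param lengths Tibble with `gene_id` and `exon_length` (bases), or a named
#'   numeric vector keyed by gene id.
#' @return Tibble of TPM values, same shape and ordering as `counts`.
#' @export
tpm <- function(counts, lengths) {
  m <- wide_to_matrix(counts)
  if (any(m < 0)) abort("counts must be non-negative")
  len <- lengths_vector(lengths, rownames(m))
  rate <- m / len
  denom <- colSums(rate)
  zero_cols <- denom == 0
  if (any(zero_cols)) {
    warn(sprintf("sample(s) with all-zero counts get all-zero TPM: %s",
                 paste(colnames(m)[zero_cols], collapse = ", ")))
    denom[zero_cols] <- 1
  }
  matrix_to_wide(sweep(rate, 2, denom, "/") * 1e6)
}

lengths_vector <- function(lengths, gene_ids) {
  if (is.data.frame(lengths)) {
    len <- setNames(lengths$exon_length, lengths$gene_id)
  } else {
    len <- lengths
  }
  len <- len[gene_ids]
  if (anyNA(len)) {
    abort(sprintf("missing gene length for: %s",
                  paste(utils::head(gene_ids[is.na(len)], 5), collapse = ", ")))
  }
  if (any(len <= 0)) abort("gene lengths must be positive")
  as.numeric(len)
}

#' Expressed-gene filter on TPM
#'
#' Keeps genes whose TPM exceeds `threshold` (strictly) in at least
#' `fraction` of samples (inclusive).
#'
#' @param tpm_tbl TPM tibble from [tpm()].
#' @param threshold TPM cutoff; comparison is strict (`>`).
#' @param fraction Minimum fraction of samples above threshold (`>=`).
#' @return Tibble with `gene_id`, `n_above`, `frac_above`, `expressed`.
#' @export
filter_expressed <- function(tpm_tbl, threshold = 1, fraction = 0.5) {
  m <- wide_to_matrix(tpm_tbl)
  n_above <- unname(rowSums(m > threshold))
  frac <- n_above / ncol(m)
  tibble(gene_id = rownames(m), n_above = as.integer(n_above),
         frac_above = frac, expressed = frac >= fraction)
}

#' Expressed gene ids
#'
#' @inheritParams filter_expressed
#' @return Character vector of gene ids passing the filter.
#' @export
expressed_genes <- function(tpm_tbl, threshold = 1, fraction = 0.5) {
  flags <- filter_expressed(tpm_tbl, threshold, fraction)
  flags$gene_id[flags$expressed]
}

#' Trimmed mean of M-values normalization factors
#'
#' Robinson-Oshlack TMM scaling factors via edgeR: the reference is the
#' sample whose upper-quartile CPM is closest to the mean upper quartile;
#' each sample's factor is the weighted mean of gene-wise log ratios
#' (M-values) after trimming the 30% most extreme M and 5% most extreme A
#' values; factors are rescaled so their geometric mean is one.
#'
#' @param counts Wide count tibble (`gene_id` + sample columns), at least
#'   two samples.
#' @return Tibble with `sample`, `lib_size`, `norm_factor`.
#' @export
tmm_factors <- function(counts) {
  m <- wide_to_matrix(counts)
  if (ncol(m) < 2L) abort("TMM normalization needs at least 2 samples")
  lib <- colSums(m)
  if (any(lib == 0)) {
    abort(sprintf("sample(s) with all-zero counts cannot be normalized: %s",
                  paste(colnames(m)[lib == 0], collapse = ", ")))
  }
  f <- edgeR::calcNormFactors(m, method = "TMM")
  tibble(sample = colnames(m), lib_size = as.numeric(lib), norm_factor = as.numeric(f))
}

#' log2 counts per million with a fixed prior count
#'
#' `log2((count + prior) / (lib_size * factor + 2 * prior) * 1e6)` with
#' prior 0.5, finite for zero counts. `factors` defaults to TMM factors
#' computed from `counts`; pass `NULL` factors of 1 via
#' `log2_cpm(counts, factors = NULL, tmm = FALSE)` style by supplying a
#' factor tibble with `norm_factor = 1`.
#'
#' @param counts Wide count tibble.
#' @param factors Factor tibble from [tmm_factors()]; computed when missing.
#' @param prior Prior count added to the numerator (and doubled in the
#'   denominator).
#' @return An expression tibble (log2 CPM), same shape as `counts`.
#' @export
log2_cpm <- function(counts, factors = tmm_factors(counts), prior = 0.5) {
  m <- wide_to_matrix(counts)
  if (is.null(factors)) {
    factors <- tibble(sample = colnames(m), lib_size = colSums(m), norm_factor = 1)
  }
  idx <- match(colnames(m), factors$sample)
  if (anyNA(idx)) abort("factors must cover every sample column")
  eff <- factors$lib_size[idx] * factors$norm_factor[idx]
  lcpm <- log2(sweep(m + prior, 2, eff + 2 * prior, "/") * 1e6)
  matrix_to_wide(lcpm)
}

#' Regress nuisance covariates out of an expression matrix
#'
#' Per gene, fits `value ~ protected terms + nuisance terms` by least squares
#' and returns the value minus the nuisance contribution; protected effects
#' (diagnosis by default) and the intercept are retained. Categorical
#' covariates are one-hot encoded against a reference level. The operation is
#' a linear projection, hence idempotent.
#'
#' @param expr Expression tibble (`gene_id` + sample columns), e.g. from
#'   [log2_cpm()].
#' @param samples Sample table with `sample_id`, a `diagnosis` column and
#'   any covariate columns.
#' @param covariates Character vector of nuisance covariate column names in
#'   `samples` to regress out.
#' @param protect Column(s) whose effects must be preserved.
#' @return Residualized expression tibble, same shape as `expr`.
#' @export
residualize <- function(expr, samples, covariates, protect = "diagnosis") {
  m <- wide_to_matrix(expr)
  samples <- as_tibble(samples)
  idx <- match(colnames(m), samples$sample_id)
  if (anyNA(idx)) abort("every expression column needs a row in `samples`")
  samples <- samples[idx, , drop = FALSE]
  missing_cov <- setdiff(c(covariates, protect), names(samples))
  if (length(missing_cov)) {
    abort(sprintf("covariate column(s) not in sample table: %s",
                  paste(missing_cov, collapse = ", ")))
  }
  if (length(covariates) == 0L) return(matrix_to_wide(m))

  X_prot <- design_columns(samples, protect)
  X_nuis <- design_columns(samples, covariates)
  X <- cbind(`(Intercept)` = 1, X_prot, X_nuis)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    bad_nuis <- intersect(aliased, colnames(X_nuis))
    if (length(bad_nuis)) {
      abort(sprintf("design matrix is rank-deficient; aliased covariate column(s): %s",
                    paste(aliased, collapse = ", ")))
    }
    abort(sprintf("design matrix is rank-deficient (aliased: %s)",
                  paste(aliased, collapse = ", ")))
  }
  beta <- qr.coef(qr_x, t(m))                       # coefficients x samples'
  nuis_cols <- colnames(X) %in% colnames(X_nuis)
  fitted_nuis <- X[, nuis_cols, drop = FALSE] %*% beta[nuis_cols, , drop = FALSE]
  matrix_to_wide(m - t(fitted_nuis))
}

# One-hot design columns for a set of sample-table variables; numeric
# columns pass through, factors/characters drop a reference level.
design_columns <- function(samples, vars) {
  blocks <- lapply(vars, function(v) {
    x <- samples[[v]]
    if (is.numeric(x)) {
      out <- matrix(x, ncol = 1, dimnames = list(NULL, v))
    } else {
      f <- factor(x)
      if (nlevels(f) < 2L) {
        return(matrix(numeric(0), nrow = length(x), ncol = 0))
      }
      out <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(out) <- paste0(v, levels(f)[-1])
    }
    out
  })
  do.call(cbind, blocks)
}

#' Collapse replicate samples to per-subject means
#'
#' Repeated measures per subject are a nuisance structure the fixed-effects
#' residualization cannot absorb; collapsing replicate columns to the subject
#' mean removes it. Samples of a subject must share one diagnosis.
#'
#' @param expr Expression tibble.
#' @param samples Sample table with `sample_id` and `subject_id`.
#' @return List with collapsed `expr` (one column per subject) and `samples`
#'   (one row per subject).
#' @export
collapse_subjects <- function(expr, samples) {
  m <- wide_to_matrix(expr)
  samples <- as_tibble(samples)[match(colnames(m), samples$sample_id), ]
  split_idx <- split(seq_len(ncol(m)), samples$subject_id)
  collapsed <- vapply(split_idx, function(i) rowMeans(m[, i, drop = FALSE]),
                      numeric(nrow(m)))
  collapsed <- matrix(collapsed, nrow = nrow(m),
                      dimnames = list(rownames(m), names(split_idx)))
  subj <- samples |>
    group_by(.data$subject_id) |>
    summarise(diagnosis = {
      if (dplyr::n_distinct(.data$diagnosis) > 1L)
        abort(sprintf("subject %s has conflicting diagnoses", .data$subject_id[1]))
      .data$diagnosis[1]
    }, .groups = "drop") |>
    mutate(sample_id = .data$subject_id, .before = 1)
  list(expr = matrix_to_wide(collapsed[, subj$subject_id, drop = FALSE]),
       samples = subj)
}

#' Normalize an exon/intron count matrix pair
#'
#' Full counts_prep pipeline: TPM filter on the exonic matrix (the surviving
#' gene set is applied to both matrices), then TMM + log2 CPM and optional
#' covariate residualization, run independently on each matrix.
#'
#' @param exon,intron Wide count tibbles sharing sample columns.
#' @param samples Sample table (`sample_id`, `diagnosis`, covariates).
#' @param lengths Composite exon lengths (see [tpm()]).
#' @param covariates Nuisance covariates to residualize out; empty for none.
#' @param tpm_threshold,tpm_fraction Expressed-gene filter parameters.
#' @param prior log-CPM prior count.
#' @return List with `exon`, `intron` (residualized log2-CPM tibbles),
#'   `factors` (per matrix), `genes` (retained ids) and `provenance`.
#' @export
prepare_counts <- function(exon, intron, samples, lengths,
                           covariates = character(),
                           tpm_threshold = 1, tpm_fraction = 0.5,
                           prior = 0.5) {
  check_samples_match(exon, intron)
  keep <- expressed_genes(tpm(exon, lengths), tpm_threshold, tpm_fraction)
  exon_f <- exon |> filter(.data$gene_id %in% keep)
  intron_f <- intron |> filter(.data$gene_id %in% keep)

  process_one <- function(cnt) {
    f <- tmm_factors(cnt)
    e <- log2_cpm(cnt, f, prior = prior)
    if (length(covariates)) e <- residualize(e, samples, covariates)
    list(expr = e, factors = f)
  }
  ex <- process_one(exon_f)
  it <- process_one(intron_f)
  list(exon = ex$expr, intron = it$expr,
       factors = list(exon = ex$factors, intron = it$factors),
       genes = keep,
       provenance = list(normalized = TRUE, residualized = length(covariates) > 0,
                         covariates = covariates, prior = prior,
                         tpm_threshold = tpm_threshold, tpm_fraction = tpm_fraction))
}
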