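# ptgr_estimator: median centering, per-group robust slopes, the delta-PTGR
# slope-contrast test (t, df = n_D + n_C, two-sided p), relative-contribution
# ratio, per-individual scores, and BH-FDR DPRG calling.

#' Median-center an expression matrix
#'
#' Subtracts each gene's median over the reference sample set from all
#' samples, producing the delta (deviation) matrix used on both the exonic
#' and intronic side. The default reference is all samples pooled across
#' groups; a control-only reference is available via the `reference`
#' argument of [estimate_ptgr()].
#'
#' @param expr Expression tibble (`gene_id` + sample columns).
#' @param reference Character vector of sample ids supplying the median;
#'   `NULL` means all samples.
#' @return Delta tibble, same shape; the reference set is recorded in the
#'   `"centering_reference"` attribute.
#' @export
median_center <- function(expr, reference = NULL) {
  m <- wide_to_matrix(expr)
  reference <- reference %||% colnames(m)
  if (length(reference) == 0L) abort("centering reference sample set is empty")
  missing <- setdiff(reference, colnames(m))
  if (length(missing)) {
    abort(sprintf("reference sample(s) not in matrix: %s",
                  paste(missing, collapse = ", ")))
  }
  med <- apply(m[, reference, drop = FALSE], 1, stats::median)
  out <- matrix_to_wide(m - med)
  attr(out, "centering_reference") <- reference
  out
}

#' Slope-contrast test for delta-PTGR
#'
#' For each gene, `delta_ptgr = slope_Disease - slope_Ctrl`,
#' `t = delta_ptgr / sqrt(SE_Disease^2 + SE_Ctrl^2)`, and the degrees of
#' freedom are `n_Disease + n_Ctrl` (the estimator's defining convention; a
#' Welch-Satterthwaite alternative is provided for sensitivity analysis).
#' Two-sided p from the Student t distribution. A degenerate pair with both
#' standard errors zero yields t = 0, p = 1 when the slopes agree and p = 0
#' with an `exact_separation` flag when they differ.
#'
#' @param fit_d,fit_c Data frames of disease and control fits with columns
#'   `slope`, `se`, `n` (rows aligned gene-for-gene; a `gene_id` column, if
#'   present, is carried through and must agree).
#' @param df_mode `"sum"` (`n_D + n_C`) or `"welch"`.
#' @return Tibble with `delta_ptgr`, `t`, `df`, `p`, `exact_separation`
#'   (plus `gene_id` when supplied).
#' @export
delta_ptgr_test <- function(fit_d, fit_c, df_mode = c("sum", "welch")) {
  df_mode <- match.arg(df_mode)
  if (nrow(fit_d) != nrow(fit_c)) abort("fit tables must be aligned row-for-row")
  if ("gene_id" %in% names(fit_d) && "gene_id" %in% names(fit_c) &&
      !identical(fit_d$gene_id, fit_c$gene_id)) {
    abort("gene_id columns of the two fit tables disagree")
  }
  delta <- fit_d$slope - fit_c$slope
  se2 <- fit_d$se^2 + fit_c$se^2
  df <- if (df_mode == "sum") {
    fit_d$n + fit_c$n
  } else {
    se2^2 / (fit_d$se^4 / pmax(fit_d$n - 2, 1) + fit_c$se^4 / pmax(fit_c$n - 2, 1))
  }
  t_stat <- ifelse(se2 > 0, delta / sqrt(se2), ifelse(delta == 0, 0, Inf * sign(delta)))
  exact_sep <- se2 == 0 & delta != 0
  p <- ifelse(is.finite(t_stat), 2 * pt(abs(t_stat), df = df, lower.tail = FALSE), 0)
  p[se2 == 0 & delta == 0] <- 1
  out <- tibble(delta_ptgr = delta, t = t_stat, df = df, p = p,
                exact_separation = exact_sep)
  if ("gene_id" %in% names(fit_d)) out <- dplyr::bind_cols(tibble(gene_id = fit_d$gene_id), out)
  out
}

#' Relative contribution of post-transcriptional dysregulation
#'
#' `ratio = |slope_Disease / slope_Ctrl - 1|`. Near-zero control slopes
#' (|slope_C| <= `epsilon`) make the ratio undefined: NA plus a flag, never
#' infinity.
#'
#' @param slope_d,slope_c Numeric vectors of disease and control slopes.
#' @param epsilon Control-slope magnitude below which the ratio is undefined.
#' @return Tibble with `ratio` and `ratio_undefined`.
#' @export
ptgr_ratio <- function(slope_d, slope_c, epsilon = 1e-6) {
  undefined <- abs(slope_c) <= epsilon
  ratio <- ifelse(undefined, NA_real_, abs(slope_d / slope_c - 1))
  tibble(ratio = ratio, ratio_undefined = undefined)
}

#' Per-individual delta-PTGR score
#'
#' `value = delta_exon_i - delta_intron_i * slope_Ctrl`: the residual of an
#' individual's exonic deviation from the control regression line. In
#' two-condition (knockdown) mode the control slope is fixed at 1.
#'
#' @param dx Individual delta-intron value(s).
#' @param dy Individual delta-exon value(s), aligned with `dx`.
#' @param slope_ctrl Control-group slope of the matched gene.
#' @return Numeric vector of per-individual scores.
#' @export
individual_ptgr <- function(dx, dy, slope_ctrl) {
  dy - dx * slope_ctrl
}

#' Call differentially post-transcriptionally regulated genes
#'
#' Benjamini-Hochberg adjusts p-values within each disease contrast and
#' flags genes with `fdr < fdr_threshold`; direction is `"up"` for positive
#' delta-PTGR (mature mRNA post-transcriptionally stabilized in disease),
#' `"down"` otherwise.
#'
#' @param records Tibble with at least `p` and `delta_ptgr` (and optionally
#'   `disease` for per-contrast adjustment and `ratio`).
#' @param fdr_threshold Significance cutoff on the adjusted p.
#' @return `records` with `fdr`, `significant`, `direction` added; the
#'   per-disease summary (DPRG count, mean |ratio|) is attached as the
#'   `"summary"` attribute and returned by [glance()] on a full fit.
#' @export
call_dprgs <- function(records, fdr_threshold = 0.05) {
  records <- as_tibble(records)
  grouping <- if ("disease" %in% names(records)) "disease" else character()
  out <- records |>
    group_by(across(all_of(grouping))) |>
    mutate(fdr = p.adjust(.data$p, method = "BH")) |>
    ungroup() |>
    mutate(significant = .data$fdr < fdr_threshold,
           direction = dplyr::if_else(.data$delta_ptgr > 0, "up", "down"))
  summary <- out |>
    group_by(across(all_of(grouping))) |>
    summarise(
      n_tested = dplyr::n(),
      n_dprg = sum(.data$significant),
      n_up = sum(.data$significant & .data$direction == "up"),
      n_down = sum(.data$significant & .data$direction == "down"),
      mean_abs_ratio = if ("ratio" %in% names(records)) mean(abs(.data$ratio), na.rm = TRUE) else NA_real_,
      .groups = "drop"
    )
  attr(out, "summary") <- summary
  out
}

fit_slopes_by_gene <- function(dy, dx, min_fit_n, psi, k, max_iter, tol) {
  genes <- rownames(dy)
  rows <- lapply(seq_along(genes), function(i) {
    fit_group_slope(dx[i, ], dy[i, ], min_fit_n = min_fit_n, psi = psi,
                    k = k, max_iter = max_iter, tol = tol)
  })
  dplyr::bind_cols(tibble(gene_id = genes), bind_rows(rows))
}

#' Estimate disease-associated changes in post-transcriptional regulation
#'
#' The core pipeline stage: median-centers the exonic and intronic log2-CPM
#' matrices, fits a per-gene robust regression of delta-exon on delta-intron
#' separately in the control group and in each disease group, and contrasts
#' the slopes. A disease slope above the control slope means mature mRNA is
#' post-transcriptionally up-regulated in disease (delta-PTGR > 0).
#'
#' @param exon,intron Expression tibbles (`gene_id` + sample columns) on the
#'   log2-CPM scale, e.g. from [prepare_counts()].
#' @param samples Sample table with `sample_id` and `diagnosis`.
#' @param control_label Diagnosis value identifying the control group.
#' @param center `"all"`: per-gene median over all samples (the default);
#'   `"control"`: median over control samples only.
#' @param df_mode `"sum"` (df = n_D + n_C) or `"welch"`.
#' @param fdr_threshold BH-FDR cutoff for DPRG calls.
#' @param epsilon Control-slope floor for the contribution ratio.
#' @inheritParams fit_group_slope
#' @return A `ptgr_fit` object: list with `records` (per gene x disease:
#'   slopes, SEs, ns, delta_ptgr, t, df, p, fdr, ratio, direction, flags),
#'   `slopes` (all per-group fits incl. control), `individual` (long tibble
#'   of per-individual scores for disease samples), `skipped` (QC table of
#'   genes excluded from testing) and `params`. Use [tidy()] / [glance()] /
#'   [autoplot()] on it.
#' @export
estimate_ptgr <- function(exon, intron, samples, control_label = "control",
                          center = c("all", "control"),
                          df_mode = c("sum", "welch"),
                          fdr_threshold = 0.05, min_fit_n = 10L,
                          psi = "huber", k = NULL, max_iter = 50L, tol = 1e-8,
                          epsilon = 1e-6) {
  center <- match.arg(center)
  df_mode <- match.arg(df_mode)
  ids <- check_samples_match(exon, intron)
  samples <- as_tibble(samples)
  if (!all(ids %in% samples$sample_id)) abort("every sample column needs a sample-table row")
  samples <- samples[match(ids, samples$sample_id), ]
  if (!control_label %in% samples$diagnosis) {
    abort(sprintf("control label '%s' absent from diagnosis column", control_label))
  }
  ctrl_ids <- samples$sample_id[samples$diagnosis == control_label]
  diseases <- setdiff(unique(samples$diagnosis), control_label)
  if (length(diseases) == 0L) abort("no disease group present")

  reference <- if (center == "all") ids else ctrl_ids
  dex <- wide_to_matrix(median_center(exon, reference))
  din <- wide_to_matrix(median_center(intron, reference))
  shared <- intersect(rownames(dex), rownames(din))
  dex <- dex[shared, , drop = FALSE]
  din <- din[shared, , drop = FALSE]

  fit_group <- function(sample_ids, label) {
    fit_slopes_by_gene(dex[, sample_ids, drop = FALSE],
                       din[, sample_ids, drop = FALSE],
                       min_fit_n, psi, k, max_iter, tol) |>
      mutate(group = label, .after = "gene_id")
  }
  ctrl_fit <- fit_group(ctrl_ids, control_label)
  disease_fits <- lapply(diseases, function(d) {
    fit_group(samples$sample_id[samples$diagnosis == d], d)
  })
  slopes <- bind_rows(c(list(ctrl_fit), disease_fits))

  usable <- function(f) !f$skipped & f$converged
  records <- purrr::map2(disease_fits, diseases, function(fd, d) {
    ok <- usable(fd) & usable(ctrl_fit)
    fd_u <- fd[ok, ]
    fc_u <- ctrl_fit[ok, ]
    stats_tbl <- delta_ptgr_test(fd_u, fc_u, df_mode = df_mode)
    ratio_tbl <- ptgr_ratio(fd_u$slope, fc_u$slope, epsilon = epsilon)
    tibble(gene_id = fd_u$gene_id, disease = d,
           slope_ctrl = fc_u$slope, se_ctrl = fc_u$se, n_ctrl = fc_u$n,
           slope_dis = fd_u$slope, se_dis = fd_u$se, n_dis = fd_u$n) |>
      dplyr::bind_cols(stats_tbl |> select(-"gene_id")) |>
      dplyr::bind_cols(ratio_tbl)
  }) |> bind_rows()
  records <- call_dprgs(records, fdr_threshold = fdr_threshold)

  skipped <- slopes |>
    filter(.data$skipped | !.data$converged) |>
    select("gene_id", "group", "n", "converged", "reason")

  ctrl_slope <- setNames(ctrl_fit$slope, ctrl_fit$gene_id)
  individual <- purrr::map2(disease_fits, diseases, function(fd, d) {
    genes <- fd$gene_id[usable(fd) & usable(ctrl_fit)]
    if (length(genes) == 0L) return(NULL)
    s_ids <- samples$sample_id[samples$diagnosis == d]
    val <- dex[genes, s_ids, drop = FALSE] -
      din[genes, s_ids, drop = FALSE] * ctrl_slope[genes]
    tibble(gene_id = rep(genes, times = length(s_ids)),
           sample_id = rep(s_ids, each = length(genes)),
           disease = d, value = as.vector(val))
  }) |> bind_rows()

  structure(list(records = records, slopes = slopes, individual = individual,
                 skipped = skipped,
                 deltas = list(exon = dex, intron = din), samples = samples,
                 params = list(control_label = control_label, center = center,
                               df_mode = df_mode, fdr_threshold = fdr_threshold,
                               min_fit_n = min_fit_n, psi = psi,
                               centering_reference = reference)),
            class = "ptgr_fit")
}

#' @export
print.ptgr_fit <- function(x, ...) {
  s <- attr(x$records, "summary")
  cat(sprintf("<ptgr_fit> %d gene x disease record(s), %d skipped fit(s)\n",
              nrow(x$records), nrow(x$skipped)))
  if (!is.null(s)) print(s)
  invisible(x)
}

#' Two-condition delta-PTGR (perturbation/knockdown mode)
#'
#' For a simple two-condition contrast (e.g. knockdown vs control organoids)
#' the change in post-transcriptional regulation per gene is the change in
#' exonic level minus the change in intronic level; equivalently the
#' per-individual score with the control slope fixed at 1. Gene-level
#' delta-PTGR is the mean score over condition samples.
#'
#' @inheritParams estimate_ptgr
#' @param condition_label Non-control condition; defaults to the single
#'   other diagnosis value.
#' @return List with `genes` (gene_id, delta_exon, delta_intron, delta_ptgr)
#'   and `individual` (long per-sample scores).
#' @export
ptgr_two_condition <- function(exon, intron, samples, control_label = "control",
                               condition_label = NULL) {
  ids <- check_samples_match(exon, intron)
  samples <- as_tibble(samples)[match(ids, as_tibble(samples)$sample_id), ]
  condition_label <- condition_label %||%
    setdiff(unique(samples$diagnosis), control_label)
  if (length(condition_label) != 1L) abort("exactly one non-control condition required")
  dex <- wide_to_matrix(median_center(exon))
  din <- wide_to_matrix(median_center(intron))
  cond_ids <- samples$sample_id[samples$diagnosis == condition_label]
  ctrl_ids <- samples$sample_id[samples$diagnosis == control_label]
  d_exon <- rowMeans(dex[, cond_ids, drop = FALSE]) - rowMeans(dex[, ctrl_ids, drop = FALSE])
  d_intron <- rowMeans(din[, cond_ids, drop = FALSE]) - rowMeans(din[, ctrl_ids, drop = FALSE])
  genes <- tibble(gene_id = rownames(dex), delta_exon = d_exon,
                  delta_intron = d_intron, delta_ptgr = d_exon - d_intron)
  indiv <- tibble(
    gene_id = rep(rownames(dex), times = length(cond_ids)),
    sample_id = rep(cond_ids, each = nrow(dex)),
    value = as.vector(dex[, cond_ids, drop = FALSE] - din[, cond_ids, drop = FALSE])
  )
  list(genes = genes, individual = indiv)
}
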