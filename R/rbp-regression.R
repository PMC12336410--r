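# rbp_regression: nominate candidate driver RBPs/miRNAs by regressing
# per-gene delta-PTGR on motif binding vectors, then summarize each
# regulator's predicted (site-bearing) targets.

#' Regress per-gene delta-PTGR on motif binding vectors
#'
#' One joint ordinary-least-squares fit of the per-gene stability measure
#' (delta-PTGR) on all motif affinity columns plus an intercept; predictors
#' are standardized (mean 0, sd 1) before fitting, so coefficients are
#' comparable across motifs. Per-coefficient t-test p-values are reported
#' raw (selection is at raw p < alpha by design); a BH column is added for
#' information only. Continuous affinity is the predictor; boolean presence
#' defines each regulator's target set and its mean target delta-PTGR.
#'
#' @param dptgr Tibble with `gene_id` and `delta_ptgr` (typically the DPRG
#'   subset of a [ptgr_fit] record table; pass the full table for the
#'   transcriptome-wide mode).
#' @param binding A `binding_matrix` from [scan_motifs()].
#' @param mode `"joint"` (one multiple regression, the default) or
#'   `"marginal"` (one simple regression per motif, for collinearity
#'   diagnostics).
#' @return An `rbp_fit` object; its `results` tibble has one row per motif:
#'   `motif_id`, `beta`, `se`, `t`, `p`, `p_bh`, `n_bound`,
#'   `mean_target_dptgr`, `dropped` (zero-variance or aliased predictors).
#' @export
regress_stability <- function(dptgr, binding, mode = c("joint", "marginal")) {
  mode <- match.arg(mode)
  dptgr <- as_tibble(dptgr)
  if (!all(c("gene_id", "delta_ptgr") %in% names(dptgr))) {
    abort("`dptgr` needs columns gene_id and delta_ptgr")
  }
  aff <- wide_to_matrix(binding$affinity)
  pres <- wide_to_matrix(binding$presence) > 0
  genes <- intersect(dptgr$gene_id, rownames(aff))
  if (length(genes) < nrow(dptgr)) {
    warn(sprintf("%d gene(s) in `dptgr` have no binding row and are dropped",
                 nrow(dptgr) - length(genes)))
  }
  if (length(genes) == 0L) abort("no genes shared between dptgr and binding matrix")
  y <- dptgr$delta_ptgr[match(genes, dptgr$gene_id)]
  X <- aff[genes, , drop = FALSE]
  pres <- pres[genes, , drop = FALSE]

  sds <- apply(X, 2, sd)
  constant <- sds == 0
  if (any(constant)) {
    warn(sprintf("dropping %d constant (zero-variance) predictor column(s): %s",
                 sum(constant), paste(colnames(X)[constant], collapse = ", ")))
  }
  Xs <- scale(X[, !constant, drop = FALSE])
  if (mode == "joint" && ncol(Xs) >= length(genes)) {
    abort(sprintf(paste("n_motifs (%d) >= n_genes (%d): cluster the PFMs first",
                        "(cluster_pfms) or use mode = 'marginal'"),
                  ncol(Xs), length(genes)))
  }

  if (mode == "joint") {
    dat <- data.frame(.y = y, Xs, check.names = FALSE)
    fit <- stats::lm(.y ~ ., data = dat)
    cf <- coef(fit)[-1]
    aliased <- names(cf)[is.na(cf)]
    if (length(aliased)) {
      warn(sprintf("dropping %d exactly collinear predictor(s): %s",
                   length(aliased), paste(gsub("`", "", aliased), collapse = ", ")))
    }
    sm <- summary(fit)$coefficients
    est <- sm[rownames(sm) != "(Intercept)", , drop = FALSE]
    rn <- gsub("`", "", rownames(est))
    stats_tbl <- tibble(motif_id = rn, beta = est[, 1], se = est[, 2],
                        t = est[, 3], p = est[, 4])
  } else {
    stats_tbl <- purrr::map(colnames(Xs), function(mid) {
      sm <- summary(stats::lm(y ~ Xs[, mid]))$coefficients
      tibble(motif_id = mid, beta = sm[2, 1], se = sm[2, 2],
             t = sm[2, 3], p = sm[2, 4])
    }) |> bind_rows()
  }

  all_ids <- colnames(aff)
  results <- tibble(motif_id = all_ids) |>
    left_join(stats_tbl, by = "motif_id") |>
    mutate(
      p_bh = p.adjust(.data$p, method = "BH"),
      n_bound = colSums(pres)[.data$motif_id],
      mean_target_dptgr = vapply(.data$motif_id, function(mid) {
        tg <- pres[, mid]
        if (!any(tg)) NA_real_ else mean(y[tg])
      }, numeric(1)),
      dropped = is.na(.data$beta)
    )
  structure(list(results = results, n_genes = length(genes), mode = mode,
                 genes = genes),
            class = "rbp_fit")
}

#' @export
print.rbp_fit <- function(x, ...) {
  cat(sprintf("<rbp_fit> %d motif(s) regressed on %d gene(s) (%s mode)\n",
              nrow(x$results), x$n_genes, x$mode))
  invisible(x)
}

#' Select and rank candidate driver regulators
#'
#' Filters regulators with raw p below `alpha` and ranks them by |beta|
#' (ties broken by motif id). The coefficient sign is the predicted
#' direction of the stability effect: positive beta means the regulator's
#' binding predicts post-transcriptional up-regulation.
#'
#' @param fit An `rbp_fit` (or its `results` tibble).
#' @param alpha Raw p-value cutoff.
#' @return Ranked tibble with a `direction` column (`"stabilizing"` /
#'   `"destabilizing"`).
#' @export
select_regulators <- function(fit, alpha = 0.05) {
  results <- if (inherits(fit, "rbp_fit")) fit$results else as_tibble(fit)
  results |>
    filter(!is.na(.data$p), .data$p < alpha) |>
    mutate(direction = dplyr::if_else(.data$beta > 0, "stabilizing", "destabilizing")) |>
    arrange(dplyr::desc(abs(.data$beta)), .data$motif_id)
}

#' Predicted targets of one regulator
#'
#' Targets are the genes whose 3'UTR carries a called binding site
#' (presence TRUE) for the motif; their mean delta-PTGR is the summary bar
#' quantity per regulator.
#'
#' @param motif_id Motif to summarize.
#' @param binding A `binding_matrix`.
#' @param dptgr Tibble with `gene_id`, `delta_ptgr`.
#' @return List with `targets` (tibble `gene_id`, `delta_ptgr`),
#'   `mean_target_dptgr` (NA with `empty = TRUE` when no targets).
#' @export
assign_targets <- function(motif_id, binding, dptgr) {
  pres <- wide_to_matrix(binding$presence) > 0
  if (!motif_id %in% colnames(pres)) {
    abort(sprintf("motif '%s' not in binding matrix", motif_id))
  }
  dptgr <- as_tibble(dptgr)
  genes <- intersect(rownames(pres)[pres[, motif_id]], dptgr$gene_id)
  targets <- dptgr |> filter(.data$gene_id %in% genes) |>
    select("gene_id", "delta_ptgr")
  list(targets = targets,
       mean_target_dptgr = if (nrow(targets)) mean(targets$delta_ptgr) else NA_real_,
       empty = nrow(targets) == 0L)
}
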