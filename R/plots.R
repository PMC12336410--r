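# ggplot2 diagnostics for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_abline geom_col
#'   geom_hline geom_vline facet_wrap labs scale_colour_manual theme_minimal
#' @export
ggplot2::autoplot

#' Volcano plot of a delta-PTGR fit
#'
#' delta-PTGR against -log10 FDR per gene, faceted by disease contrast,
#' with DPRGs highlighted.
#'
#' @param object A `ptgr_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ptgr_fit <- function(object, ...) {
  rec <- tidy(object)
  ggplot(rec, aes(x = .data$delta_ptgr, y = -log10(.data$fdr),
                  colour = .data$significant)) +
    geom_point(alpha = 0.5, size = 0.8) +
    geom_hline(yintercept = -log10(object$params$fdr_threshold),
               linetype = "dashed", colour = "grey40") +
    scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                        name = "DPRG") +
    facet_wrap(~disease) +
    labs(x = expression(Delta * "PTGR (slope difference)"),
         y = expression(-log[10] ~ "FDR")) +
    theme_minimal()
}

#' Per-gene slope diagnostic: delta-exon vs delta-intron
#'
#' Scatter of the centered exonic against intronic values for one gene,
#' with the fitted robust line per group (the schematic the slope contrast
#' summarizes).
#'
#' @param fit A `ptgr_fit`.
#' @param gene Gene id to plot.
#' @return A ggplot.
#' @export
plot_gene_slopes <- function(fit, gene) {
  stopifnot(inherits(fit, "ptgr_fit"))
  dex <- fit$deltas$exon
  din <- fit$deltas$intron
  if (!gene %in% rownames(dex)) abort(sprintf("gene '%s' not in fit", gene))
  samples <- fit$samples
  df <- tibble(sample_id = colnames(dex),
               delta_intron = din[gene, ], delta_exon = dex[gene, ]) |>
    left_join(samples |> select("sample_id", "diagnosis"), by = "sample_id")
  lines <- fit$slopes |> filter(.data$gene_id == gene, !.data$skipped)
  ggplot(df, aes(x = .data$delta_intron, y = .data$delta_exon,
                 colour = .data$diagnosis)) +
    geom_point(alpha = 0.7) +
    geom_abline(data = lines,
                aes(slope = .data$slope, intercept = .data$intercept,
                    colour = .data$group)) +
    labs(title = gene, x = expression(Delta * "intron (log2)"),
         y = expression(Delta * "exon (log2)"), colour = NULL) +
    theme_minimal()
}

#' Coefficient plot of selected driver regulators
#'
#' Standardized regression coefficients of regulators passing the selection
#' cutoff, signed by predicted stability effect.
#'
#' @param object An `rbp_fit`.
#' @param alpha Raw-p selection cutoff.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rbp_fit <- function(object, alpha = 0.05, ...) {
  sel <- select_regulators(object, alpha = alpha)
  if (nrow(sel) == 0L) abort("no regulators selected at this alpha")
  sel$motif_id <- factor(sel$motif_id, levels = rev(sel$motif_id))
  ggplot(sel, aes(x = .data$beta, y = .data$motif_id, fill = .data$direction)) +
    geom_col() +
    geom_vline(xintercept = 0, colour = "grey40") +
    labs(x = "standardized coefficient (effect on ΔPTGR)", y = NULL,
         fill = NULL) +
    theme_minimal()
}
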