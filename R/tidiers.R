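# broom-style accessors for fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a delta-PTGR fit
#'
#' @param x A `ptgr_fit` from [estimate_ptgr()].
#' @param ... Unused.
#' @return The per-gene, per-disease record tibble (slopes, SEs, t, df, p,
#'   fdr, ratio, direction, flags).
#' @export
tidy.ptgr_fit <- function(x, ...) {
  out <- x$records
  attr(out, "summary") <- NULL
  out
}

#' One-row-per-contrast summary of a delta-PTGR fit
#'
#' @inheritParams tidy.ptgr_fit
#' @return Tibble with one row per disease contrast: genes tested, DPRG
#'   counts by direction, mean |ratio|.
#' @export
glance.ptgr_fit <- function(x, ...) {
  attr(x$records, "summary")
}

#' Tidy a regulator regression fit
#'
#' @param x An `rbp_fit` from [regress_stability()].
#' @param ... Unused.
#' @return Per-motif coefficient tibble.
#' @export
tidy.rbp_fit <- function(x, ...) x$results

#' One-row summary of a regulator regression fit
#'
#' @inheritParams tidy.rbp_fit
#' @param alpha Raw-p cutoff used for the selected count.
#' @return One-row tibble: motifs fitted/dropped, genes, selected count.
#' @export
glance.rbp_fit <- function(x, alpha = 0.05, ...) {
  tibble(n_motifs = nrow(x$results),
         n_dropped = sum(x$results$dropped),
         n_genes = x$n_genes,
         n_selected = sum(!is.na(x$results$p) & x$results$p < alpha),
         mode = x$mode)
}
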