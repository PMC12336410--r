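# introdelta

Bulk RNA-seq measures two transcript pools at once: reads over introns
come from unspliced pre-mRNA and track **transcription**, while reads over
exons come from mature mRNA and track transcription **plus everything
downstream** — decay, RBP-mediated stabilization, miRNA repression.
`introdelta` exploits this split to estimate, gene by gene, how much of a
disease-associated expression change is **post-transcriptional**, and to
nominate the RNA-binding proteins and miRNAs most likely driving it. It is
aimed at transcriptomics analysts with case/control (or
perturbation/control) count matrices from rRNA-depleted libraries.

## The statistic

Per gene, exonic and intronic log2-CPM values are median-centered into
deviations Δexon and Δintron, and a Huber robust regression
Δexon ~ Δintron is fitted within each diagnosis group. The slope *b*
measures how tightly mature-mRNA variation follows pre-mRNA variation in
that group. The disease-control contrast is

    ΔPTGR = b_D − b_C
    t     = (b_D − b_C) / sqrt(SE_D² + SE_C²),   df = n_D + n_C

with two-sided Student-t p-values, BH-adjusted per disease; genes at
FDR < 0.05 are differentially post-transcriptionally regulated (DPRGs).
ΔPTGR > 0 means mature mRNA is stabilized in disease. The package also
reports the relative-contribution ratio |b_D/b_C − 1|, per-individual
scores Δexonᵢ − Δintronᵢ·b_C, and — downstream — per-motif regression of
ΔPTGR on 3'UTR binding affinity to rank candidate driver regulators.

## Worked example

Everything is testable without external data via the built-in simulator,
which draws negative-binomial exon/intron counts with known per-gene,
per-group slopes:

```r
library(introdelta)
library(dplyr)

cfg <- sim_config(seed = 2024, n_genes = 500, n_ctrl = 60, n_disease = 60,
                  perturbed_fraction = 0.1, delta = 0.5)
sim  <- simulate_counts(cfg)                                   # counts + truth
prep <- prepare_counts(sim$exon, sim$intron, sim$samples,      # TPM filter,
                       sim$truth$genes)                        # TMM, log2 CPM
fit  <- estimate_ptgr(prep$exon, prep$intron, sim$samples)     # slope contrast

glance(fit)
#> # A tibble: 1 × 6
#>   disease n_tested n_dprg  n_up n_down mean_abs_ratio
#> 1 disease      500     48    44      4          0.138

tidy(fit) |> filter(significant) |> arrange(fdr) |> head(3) |>
  select(gene_id, slope_ctrl, slope_dis, delta_ptgr, t, df, fdr, direction)
#>   gene_id slope_ctrl slope_dis delta_ptgr     t    df        fdr direction
#> 1 g0396        0.643      1.25      0.607  6.91   120    1.27e-7 up
#> 2 g0247        0.696      1.36      0.668  6.59   120    3.03e-7 up
#> 3 g0072        0.738      1.37      0.632  6.24   120    1.13e-6 up

truth_eval(tidy(fit), sim$truth)[, c("sensitivity", "fdp", "direction_accuracy")]
#>   sensitivity   fdp direction_accuracy
#> 1        0.86 0.104                  1
```

Fifty genes were simulated with a true slope shift of +0.5; at BH-FDR 0.05
the pipeline recalls 86% of them with ~10% false discoveries, and every
true positive is called in the correct (up) direction. `autoplot(fit)`
draws the volcano per contrast and `plot_gene_slopes(fit, "g0396")` the
underlying two-group scatter with fitted lines.

The motif layer follows the same pattern: `read_pfms()` /
`cluster_pfms()` build a non-redundant RBP motif set, `scan_motifs()`
turns 3'UTR FASTA into a genes × motifs affinity/presence matrix,
`regress_stability()` fits ΔPTGR on the binding vectors, and
`select_regulators()` ranks significant drivers;
`mirna_seed_pattern()` + `kmer_site_counts()` + `enrichment_test()`
handle miRNA seed and AU-rich-element enrichment. A thin CLI
(`exec/introdelta`) exposes each stage (`simulate`, `build-annotation`,
`normalize`, `estimate-ptgr`, `scan-motifs`, `test-enrichment`,
`infer-rbps`) for file-based pipelines.

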