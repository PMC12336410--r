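---
title: "Estimating post-transcriptional dysregulation from exon and intron counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating post-transcriptional dysregulation from exon and intron counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introdelta)
library(dplyr)
```

## The model

Bulk RNA-seq reads split into two informative pools. Reads over intronic
bases come from pre-mRNA that has not yet been spliced, so their abundance
tracks transcription. Reads over exonic bases come (mostly) from mature
mRNA, whose abundance reflects transcription *and* everything that happens
afterwards — decay, stabilization by RNA-binding proteins (RBPs),
miRNA-mediated degradation. Contrasting the two pools therefore isolates
the post-transcriptional component of an expression change.

Concretely, for each gene we center the exonic and intronic log2-CPM
values on their median across the reference sample set, giving per-sample
deviations $\Delta \mathrm{exon}$ and $\Delta \mathrm{intron}$. Within
each diagnosis group we fit a robust straight line

$$\Delta \mathrm{exon} = a + b\, \Delta \mathrm{intron} + \varepsilon$$

and read the slope $b$ as the coupling between pre-mRNA and mature-mRNA
variation in that group. The disease-vs-control contrast is

$$\Delta\mathrm{PTGR} = b_{\mathrm{Disease}} - b_{\mathrm{Ctrl}}, \qquad
t = \frac{b_{\mathrm{Disease}} - b_{\mathrm{Ctrl}}}
         {\sqrt{SE_{\mathrm{Disease}}^2 + SE_{\mathrm{Ctrl}}^2}}, \qquad
df = n_{\mathrm{Disease}} + n_{\mathrm{Ctrl}},$$

with a two-sided Student-t p-value, BH-adjusted within each disease
contrast; genes with FDR < 0.05 are called differentially
post-transcriptionally regulated (DPRGs). A positive $\Delta$PTGR means
mature mRNA is relatively stabilized in disease. Two companion
quantities are reported per gene: the relative-contribution ratio
$\left|b_{\mathrm{Disease}}/b_{\mathrm{Ctrl}} - 1\right|$ (undefined, and
flagged, when $|b_{\mathrm{Ctrl}}| \le 10^{-6}$ — never reported as
infinity), and the per-individual score
$\Delta\mathrm{exon}_i - \Delta\mathrm{intron}_i \cdot b_{\mathrm{Ctrl}}$,
the residual of individual $i$ from the control line.

The `df = n_D + n_C` convention is kept because it is the definition this
pipeline reproduces; a Welch–Satterthwaite alternative (`df_mode =
"welch"`) is provided for sensitivity analysis and gives slightly smaller
df, which matters only at very small group sizes.

### Assumptions and when they fail

* Intronic reads must be abundant enough to estimate per-sample pre-mRNA
  levels; rRNA-depleted libraries are assumed. Poly-A-selected data will
  underrepresent introns and inflate slope SEs.
* The slope model assumes the exon–intron coupling is linear on the log2
  scale within a group. Genes with bimodal regulation or strong
  isoform switching violate this; the robust loss limits, but does not
  remove, their influence.
* Median centering uses all samples by default (`center = "all"`). With
  severely unbalanced group sizes, a control-only reference
  (`center = "control"`) anchors the deltas to the control distribution;
  slopes are unaffected by the choice, intercepts and individual scores
  shift.

## Normalization choices

Counts are prepared with the standard bulk workflow: genes are kept when
exonic TPM exceeds 1 (strictly) in at least half the samples (the filter
is computed on exonic TPM only and applied to both matrices), TMM scaling
factors are computed per matrix with edgeR (trim 30% of M-values, 5% of
A-values, upper-quartile reference, factors rescaled to geometric mean 1),
and expression is transformed as

$$\log_2 \frac{\mathrm{count} + 0.5}
              {\mathrm{lib} \cdot f + 1} \times 10^6,$$

a fixed prior count of 0.5 keeping zero counts finite. The exonic and
intronic matrices are processed independently end to end.

Nuisance covariates are removed per gene by least squares, protecting the
diagnosis term: the full design (intercept + protected + nuisance, with
one-hot coding of categorical covariates) is fit once per gene and only
the nuisance contribution is subtracted. This is a linear projection, so
it is idempotent, and a rank-deficient design fails loudly with the
aliased columns named. Which covariates to remove is user configuration:
upstream covariate selection (MARS-style screening over a covariate
superset) is deliberately out of scope, because downstream stages consume
only the chosen list. A subject-level random effect is approximated by
fixed-effects residualization; when subjects have replicate samples,
`collapse_subjects()` averages them first, which removes the dominant
repeated-measures structure without a mixed-model dependency.

## Robust fit numerics

The per-group line is Huber M-estimated by iteratively reweighted least
squares: tuning constant 1.345 (95% Gaussian efficiency), at most 50
iterations, relative coefficient tolerance 1e-8, scale re-estimated each
iteration as the MAD of residuals with a 1e-8 floor (the floor makes
exact-fit configurations — e.g. a clean line plus gross outliers — behave
as hard outlier rejection rather than dividing by zero). Tukey bisquare
(c = 4.685) is available behind the `psi` argument. The slope SE is the
standard M-estimation asymptotic covariance with Huber's small-sample
correction; the null-calibration property below checks empirically that
this SE yields uniform p-values under the null.

Genes are gated before fitting: at least `min_fit_n = 10` finite pairs per
group and a positive MAD of the predictor; gated genes appear in the QC
table with a reason, never silently vanish. An intercept is always
estimated — centering makes it near zero, but forcing the line through the
origin would be a stronger assumption than the slope contrast needs.

## Motif layer

RBP motifs are position frequency matrices (PFMs), read from MEME motif
format or a plain 4-column table, floored at probability 1e-3 and
renormalized per position. Scanning a 3'UTR computes every window's
probability product; the reported **affinity** is log2 of the window-score
sum (an occupancy-like total, smooth in sequence length), and **presence**
— the binding-site call that defines an RBP's target genes — requires the
best window to reach 80% of the motif's maximum attainable window score.
That fraction is an exposed tuning constant (`presence_fraction`), chosen
so that a single strong site suffices and point-degraded sites still
qualify; it is deliberately conservative because target sets feed mean
delta-PTGR summaries. Only genes whose isoforms share one 3'UTR start are
eligible for scanning, to keep alternative splicing from blurring UTR
content; the start is taken from CDS ends (or explicit three-prime-UTR
features) per transcript.

Motif redundancy is removed before regression: similarity between two
PFMs is the Pearson correlation of their affinity profiles over a fixed
panel of 500 random length-100 sequences (seeded, so the measure is
deterministic and symmetric), and greedy clustering in input order at
similarity 0.75 keeps each cluster's first member as representative.
Degenerate motifs with constant profiles (e.g. near-uniform PFMs)
correlate with nothing and are assigned similarity 0, flagged.

Driver inference is one joint OLS of per-gene delta-PTGR on all motif
affinity columns (standardized to mean 0, sd 1), intercept included.
Regulators are selected at raw p < 0.05 — by design no multiple-testing
correction, matching the selection rule this pipeline reproduces; a BH
column is emitted for information. Continuous affinity is the regression
predictor while boolean presence defines target sets: the two roles are
kept separate on purpose. miRNAs enter the same machinery via seed-match
patterns: the searched site is the reverse complement of seed bases 2–8
(7mer-m8 default; 8mer and 7mer-A1 variants available), with AU-rich
elements as the AUUUA pentamer by default.

## What the simulator emulates, and what it does not

`simulate_counts()` draws, per gene, a baseline intronic log2 mean from
N(6.5, 1.2) and a control slope from N(1, 0.1); per sample, latent
intronic values get N(0, 1) spread, exonic values follow the group's slope
plus N(0, residual sd) noise, and counts are negative-binomial with mean
$2^{\mathrm{latent}} \times \mathrm{lib}/10^6$, dispersion 0.05, library
sizes uniform on [5e6, 2e7]. The study-scale defaults — 2000 genes,
100 + 100 samples, 10% of genes with a slope shift of +0.5, residual sd
0.3 — are the conditions under which the package's statistical properties
are validated: null calibration (fraction of raw p < 0.05 within
[0.03, 0.07]), recovery (sensitivity ≥ 0.8 and observed FDP ≤ 0.10 at
BH-FDR 0.05), and direction fidelity. The baseline/dispersion/library
values were fixed once as typical of rRNA-depleted bulk brain data with
moderate sequencing depth.

Counts are simulated at the count level rather than on the log scale
precisely so the TPM filter, TMM factors and log-CPM transform are
genuinely exercised. Note one consequence: count-level noise enters both
axes of the slope fit, so estimated slopes are mildly attenuated
(errors-in-variables); the attenuation is common to both groups and
cancels in the contrast and in the ratio, which the recovery results
confirm. The mean relative-contribution ratio, however, is inflated
additively by slope noise (|x| of a noisy zero is positive), so its
agreement with the truth-implied mean is checked in a low-noise
configuration (residual sd 0.05, dispersion 0.001) where the estimator's
convergence — rather than the noise floor — is under test.

The simulator does **not** emulate: isoform structure or splicing
variation, gene–gene expression correlation, GC/length biases,
subject-level replicate structure (unless covariates are configured),
exonic reads contaminating introns, or empirical PFM composition. Passing
tests therefore certify the estimator's statistical behavior under its
own model, not robustness to every artifact of real libraries.

## Degenerate inputs and tie-breaks

* Zero-SE slope pairs: equal slopes give t = 0, p = 1; unequal slopes give
  p = 0 with an `exact_separation` flag rather than NaN.
* All-zero sample columns: TPM warns and returns zeros; TMM refuses, naming
  the sample.
* Regulator ranking ties in |beta| break lexicographically by motif id, so
  output is reproducible.
* Fisher odds ratios use the Haldane 0.5 correction only when a table cell
  is zero, flagged, never silently.
* Sequences shorter than a motif score affinity 0 (flagged), not missing.

## Problem sizes

All statistical validation runs at the study-scale defaults above
(2000 genes, 200 samples; 50 motifs over 2000 UTRs of 200 nt for the
driver layer; 600 UTRs for the seed-enrichment check), which a single CPU
completes in a few minutes. Unit tests use smaller fixtures (tens to
hundreds of genes) whose expected values come from independent brute-force
oracles computed in the test code.

## Limitations

* delta-PTGR is a relative quantity: a global, gene-uniform stability
  shift moves all slopes together and is absorbed by normalization.
* The per-individual score inherits the control slope's estimation error;
  it is a screening quantity, not an effect-size estimate.
* The driver regression is associative. Shared sequence composition
  between motifs (AU-rich families especially) can split or transfer
  credit; the clustering step reduces but cannot eliminate this, and the
  marginal mode exists to diagnose it.
* Two-condition (knockdown) mode fixes the control slope at 1, i.e. it
  assumes unit exon–intron coupling; with few replicates this is the only
  identifiable choice, but it conflates coupling changes with stability
  changes.
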