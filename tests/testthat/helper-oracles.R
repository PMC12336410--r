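# Independent oracles and fixture builders. Oracles are deliberately
# brute-force / step-by-step re-implementations, kept free of the package
# code paths they check.

# ---- interval oracles (per-base membership on toy genes) ----

# logical coverage vector over [span_start, span_end) from raw intervals
perbase_coverage <- function(starts, ends, span_start, span_end) {
  cov <- rep(FALSE, span_end - span_start)
  for (i in seq_along(starts)) {
    lo <- max(starts[i], span_start)
    hi <- min(ends[i], span_end)
    if (hi > lo) cov[(lo - span_start + 1):(hi - span_start)] <- TRUE
  }
  cov
}

# random toy gene: returns list(gtf lines, exon interval table, span)
random_toy_gene <- function(gene_id, chrom = "chr1", strand = "+",
                            span_len = 10000L, n_tx = 5L) {
  span_start <- sample.int(1000L, 1)
  span_end <- span_start + span_len
  lines <- sprintf('%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
                   chrom, span_start + 1L, span_end, strand, gene_id)
  exon_tbl <- NULL
  for (t in seq_len(n_tx)) {
    tx <- sprintf("%s.t%d", gene_id, t)
    n_ex <- sample(1:4, 1)
    for (e in seq_len(n_ex)) {
      s <- span_start + sample.int(span_len - 200L, 1)
      w <- sample(50:400, 1)
      en <- min(s + w, span_end)
      lines <- c(lines, sprintf(
        '%s\tsim\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
        chrom, s + 1L, en, strand, gene_id, tx))
      exon_tbl <- rbind(exon_tbl, data.frame(start = s, end = en))
    }
  }
  list(gtf = lines, exons = exon_tbl, span = c(span_start, span_end))
}

# ---- TMM oracle: step-by-step trimmed-mean-of-M-values ----

tmm_oracle <- function(counts) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  f75 <- vapply(seq_len(ncol(counts)),
                function(i) unname(quantile(counts[, i] / lib[i], 0.75)),
                numeric(1))
  ref <- which.min(abs(f75 - mean(f75)))
  one_factor <- function(i) {
    obs <- counts[, i]; rf <- counts[, ref]
    nO <- obs / lib[i]; nR <- rf / lib[ref]
    logR <- log2(nO / nR)
    absE <- (log2(nO) + log2(nR)) / 2
    v <- (lib[i] - obs) / (lib[i] * obs) + (lib[ref] - rf) / (lib[ref] * rf)
    fin <- is.finite(logR) & is.finite(absE) & (absE > -1e10)
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * 0.3) + 1; hiL <- n + 1 - loL
    loS <- floor(n * 0.05) + 1; hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    f <- sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
    2^f
  }
  f <- vapply(seq_len(ncol(counts)), one_factor, numeric(1))
  f / exp(mean(log(f)))
}

# ---- Benjamini-Hochberg stepwise-minimum oracle ----

bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running_min <- Inf
  for (i in rev(seq_len(m))) {
    running_min <- min(running_min, m * p[ord[i]] / i)
    adj[ord[i]] <- min(running_min, 1)
  }
  adj
}

# ---- hypergeometric tail oracle for one-sided Fisher ----

hyper_tail_oracle <- function(hits_in_set, set_size, hits_total, universe) {
  k_max <- min(set_size, hits_total)
  sum(stats::dhyper(hits_in_set:k_max, hits_total, universe - hits_total, set_size))
}

# ---- brute-force PFM window scan oracle ----

scan_oracle <- function(pfm, seq) {
  bases <- strsplit(chartr("uU", "TT", toupper(seq)), "")[[1]]
  L <- nrow(pfm)
  scores <- vapply(seq_len(length(bases) - L + 1L), function(s) {
    pr <- 1
    for (j in seq_len(L)) {
      b <- match(bases[s + j - 1L], c("A", "C", "G", "T"))
      pr <- pr * if (is.na(b)) 0 else pfm[j, b]
    }
    pr
  }, numeric(1))
  list(affinity = log2(sum(scores)), best = max(scores))
}

# ---- small simulation fixture shared by fast tests ----

small_sim <- function(seed = 5, n_genes = 120, n_ctrl = 25, n_disease = 25,
                      perturbed_fraction = 0.2, ...) {
  simulate_counts(sim_config(seed = seed, n_genes = n_genes, n_ctrl = n_ctrl,
                             n_disease = n_disease,
                             perturbed_fraction = perturbed_fraction, ...))
}
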