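# motif_toolkit, part 2: 3'UTR sequence handling, PFM affinity scanning,
# IUPAC k-mer / miRNA seed matching, and Fisher enrichment testing.
# Sequences are normalized internally to the DNA alphabet (U -> T);
# 3'UTRs are scanned on the given (sense) strand only.

normalize_seq <- function(seq) {
  chartr("uU", "TT", toupper(seq))
}

#' Read 3'UTR sequences from FASTA
#'
#' @param file FASTA path (record ids are taken up to the first whitespace
#'   and used as gene ids). RNA alphabets are normalized to DNA.
#' @return Tibble with `gene_id`, `seq`, `length`.
#' @export
read_utrs <- function(file) {
  ss <- Biostrings::readBStringSet(file)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- normalize_seq(as.character(ss))
  tibble(gene_id = ids, seq = unname(seqs), length = nchar(seqs))
}

#' Write sequences as FASTA
#'
#' @param utrs Tibble with `gene_id` and `seq`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_utrs <- function(utrs, file) {
  ss <- Biostrings::DNAStringSet(setNames(normalize_seq(utrs$seq), utrs$gene_id))
  Biostrings::writeXStringSet(ss, file)
  invisible(file)
}

#' Scan one sequence with one PFM
#'
#' Every window of motif width gets the product of its per-position base
#' probabilities. The affinity is `log2` of the sum of window scores
#' (energy-like total occupancy); presence is called when the best window
#' reaches `presence_fraction` of the motif's maximum attainable window
#' score. Sequences shorter than the motif return affinity 0 and no
#' presence, flagged. Non-alphabet characters score as zero-probability
#' bases with one warning per sequence.
#'
#' @param pfm Position-probability matrix (positions x 4, A C G T).
#' @param seq Character sequence (DNA or RNA alphabet).
#' @param presence_fraction Fraction of the maximum attainable window score
#'   required to call a binding site.
#' @return List: `affinity`, `presence`, `best_start` (0-based), `best_score`
#'   (window probability product), `max_attainable`, `flag` (NA, "short_seq"
#'   or "no_scorable_window").
#' @export
scan_affinity <- function(pfm, seq, presence_fraction = 0.8) {
  seq <- normalize_seq(seq)
  L <- nrow(pfm)
  S <- nchar(seq)
  max_attain <- prod(apply(pfm, 1, max))
  if (S < L) {
    return(list(affinity = 0, presence = FALSE, best_start = NA_integer_,
                best_score = NA_real_, max_attainable = max_attain,
                flag = "short_seq"))
  }
  code <- match(strsplit(seq, "", fixed = TRUE)[[1]], PFM_BASES)
  if (anyNA(code)) {
    warn(sprintf("sequence contains %d non-ACGTU character(s); windows covering them score 0",
                 sum(is.na(code))))
  }
  lp <- log2(pfm)
  nw <- S - L + 1L
  ls <- numeric(nw)
  for (j in seq_len(L)) {
    contrib <- unname(lp[j, ])[code[j:(j + nw - 1L)]]
    contrib[is.na(contrib)] <- -Inf
    ls <- ls + contrib
  }
  scores <- 2^ls
  total <- sum(scores)
  if (total == 0) {
    return(list(affinity = 0, presence = FALSE, best_start = NA_integer_,
                best_score = 0, max_attainable = max_attain,
                flag = "no_scorable_window"))
  }
  best <- which.max(scores)
  list(affinity = log2(total), presence = scores[best] >= presence_fraction * max_attain,
       best_start = best - 1L, best_score = scores[best],
       max_attainable = max_attain, flag = NA_character_)
}

#' Scan a UTR set with a PFM set into a binding matrix
#'
#' @param utrs Tibble with `gene_id` and `seq` (see [read_utrs()]); if an
#'   `eligible` column is present, ineligible genes are dropped first.
#' @param pfms A `pfm_set`.
#' @inheritParams scan_affinity
#' @return A `binding_matrix`: list with `affinity` and `presence` wide
#'   tibbles (`gene_id` + one column per motif) and `sites` (best-window
#'   calls: `gene_id`, `motif_id`, `start`, `end`, `score`; 0-based
#'   half-open, gene-relative).
#' @export
scan_motifs <- function(utrs, pfms, presence_fraction = 0.8) {
  utrs <- as_tibble(utrs)
  if ("eligible" %in% names(utrs)) utrs <- filter(utrs, .data$eligible)
  if (nrow(utrs) == 0L) abort("no (eligible) UTR sequences to scan")
  aff <- matrix(0, nrow(utrs), nrow(pfms),
                dimnames = list(utrs$gene_id, pfms$motif_id))
  pres <- aff > 1
  sites <- list()
  for (mi in seq_len(nrow(pfms))) {
    m <- pfms$pfm[[mi]]
    res <- lapply(utrs$seq, scan_affinity, pfm = m,
                  presence_fraction = presence_fraction)
    aff[, mi] <- vapply(res, `[[`, numeric(1), "affinity")
    pres[, mi] <- vapply(res, `[[`, logical(1), "presence")
    hit <- which(pres[, mi])
    if (length(hit)) {
      st <- vapply(res[hit], `[[`, integer(1), "best_start")
      sites[[pfms$motif_id[mi]]] <- tibble(
        gene_id = utrs$gene_id[hit], motif_id = pfms$motif_id[mi],
        start = st, end = st + nrow(m),
        score = vapply(res[hit], `[[`, numeric(1), "best_score"))
    }
  }
  structure(list(affinity = matrix_to_wide(aff), presence = matrix_to_wide(pres),
                 sites = bind_rows(sites),
                 params = list(presence_fraction = presence_fraction)),
            class = "binding_matrix")
}

#' @export
print.binding_matrix <- function(x, ...) {
  cat(sprintf("<binding_matrix> %d gene(s) x %d motif(s); %d site call(s)\n",
              nrow(x$affinity), ncol(x$affinity) - 1L, nrow(x$sites)))
  invisible(x)
}

#' Count (possibly overlapping) IUPAC pattern sites in a sequence
#'
#' @param pattern Fixed pattern, IUPAC ambiguity letters allowed (e.g. the
#'   ARE pentamer `"ATTTA"`/`"AUUUA"`).
#' @param seq Sequence to search (DNA or RNA alphabet).
#' @return Tibble of matches with `start`, `end` (0-based half-open); the
#'   match count is `nrow()` of the result.
#' @export
kmer_sites <- function(pattern, seq) {
  pattern <- normalize_seq(pattern)
  if (nchar(pattern) == 0L) abort("pattern must be non-empty")
  bad <- setdiff(strsplit(pattern, "")[[1]], names(Biostrings::IUPAC_CODE_MAP))
  if (length(bad)) {
    abort(sprintf("invalid IUPAC letter(s) in pattern: %s", paste(bad, collapse = ", ")))
  }
  hits <- Biostrings::matchPattern(pattern, Biostrings::DNAString(normalize_seq(seq)),
                                   fixed = FALSE)
  tibble(start = Biostrings::start(hits) - 1L, end = Biostrings::end(hits))
}

#' Per-gene k-mer site counts over a UTR set
#'
#' @param utrs Tibble with `gene_id`, `seq`.
#' @inheritParams kmer_sites
#' @return Tibble with `gene_id`, `n_sites`, `has_site`.
#' @export
kmer_site_counts <- function(utrs, pattern) {
  n <- vapply(utrs$seq, function(s) nrow(kmer_sites(pattern, s)), integer(1),
              USE.NAMES = FALSE)
  tibble(gene_id = utrs$gene_id, n_sites = n, has_site = n > 0L)
}

#' miRNA seed-site pattern (reverse complement of the seed)
#'
#' A target site is the reverse complement of the miRNA seed region:
#' `"7mer-m8"` uses bases 2-8; `"8mer"` appends the A opposite base 1;
#' `"7mer-A1"` uses bases 2-7 plus that A.
#'
#' @param mirna Mature miRNA sequence, 5' to 3' (RNA or DNA alphabet).
#' @param type Site type.
#' @return DNA pattern to search in 3'UTRs.
#' @export
mirna_seed_pattern <- function(mirna, type = c("7mer-m8", "8mer", "7mer-A1")) {
  type <- match.arg(type)
  m <- normalize_seq(mirna)
  if (nchar(m) < 8L) abort("miRNA sequence must be at least 8 bases")
  rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  switch(type,
         "7mer-m8" = rc(substr(m, 2, 8)),
         "8mer" = paste0(rc(substr(m, 2, 8)), "A"),
         "7mer-A1" = paste0(rc(substr(m, 2, 7)), "A"))
}

#' Fisher's exact enrichment test on a gene set
#'
#' Tests whether `hits_in_set` of `set_size` genes is enriched relative to
#' `hits_total` of `universe_size`. The odds ratio is the sample
#' (cross-product) ratio; a Haldane 0.5 continuity correction is applied
#' only when some cell of the 2x2 table is zero (flagged).
#'
#' @param hits_in_set,set_size,hits_total,universe_size 2x2 table margins.
#' @param sided `"greater"` (one-sided enrichment, the default) or `"two"`.
#' @return One-row tibble: `odds_ratio`, `p`, `haldane`.
#' @export
enrichment_test <- function(hits_in_set, set_size, hits_total, universe_size,
                            sided = c("greater", "two")) {
  sided <- match.arg(sided)
  if (universe_size <= 0) abort("universe_size must be positive")
  if (set_size <= 0) abort("gene set is empty")
  if (set_size > universe_size) abort("set_size exceeds universe_size")
  a <- hits_in_set
  b <- set_size - a
  c_ <- hits_total - a
  d <- (universe_size - set_size) - c_
  if (min(a, b, c_, d) < 0) abort("inconsistent 2x2 table margins")
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE)
  p <- fisher.test(tab, alternative = if (sided == "greater") "greater" else "two.sided")$p.value
  haldane <- any(tab == 0)
  h <- if (haldane) 0.5 else 0
  or <- ((a + h) * (d + h)) / ((b + h) * (c_ + h))
  tibble(odds_ratio = or, p = p, haldane = haldane)
}
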