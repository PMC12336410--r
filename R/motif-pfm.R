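# motif_toolkit, part 1: PFM containers, I/O (MEME motif format and a plain
# 4-column probability table), similarity on a shared random-sequence panel,
# and greedy clustering into a non-redundant motif set.

PFM_BASES <- c("A", "C", "G", "T")

#' Construct a PFM set
#'
#' @param matrices Named list of position-probability matrices (positions x
#'   4, columns A, C, G, U/T). Rows are floored at pseudocount 1e-3 and
#'   renormalized to sum to one.
#' @param names Optional RBP/miRNA display names (defaults to motif ids).
#' @return A `pfm_set` tibble: `motif_id`, `name`, `length`, `pfm`
#'   (list-column of normalized matrices).
#' @export
pfm_set <- function(matrices, names = NULL) {
  ids <- base::names(matrices)
  if (is.null(ids)) abort("`matrices` must be a named list keyed by motif id")
  names <- names %||% ids
  mats <- purrr::map2(matrices, ids, normalize_pfm)
  structure(
    tibble(motif_id = ids, name = names,
           length = vapply(mats, nrow, integer(1)),
           pfm = unname(mats)),
    class = c("pfm_set", class(tibble()))
  )
}

normalize_pfm <- function(m, id, pseudo = 1e-3) {
  m <- as.matrix(m)
  if (ncol(m) != 4L) abort(sprintf("motif %s: PFM must have 4 base columns", id))
  if (nrow(m) < 3L) abort(sprintf("motif %s: PFM length %d < 3", id, nrow(m)))
  rs <- rowSums(m)
  if (any(rs == 0)) {
    abort(sprintf("motif %s: position %d sums to 0", id, which(rs == 0)[1]))
  }
  if (any(m < 0)) abort(sprintf("motif %s: negative probabilities", id))
  m <- m / rs
  m[m < pseudo] <- pseudo
  m <- m / rowSums(m)
  dimnames(m) <- list(NULL, PFM_BASES)
  m
}

#' Read PFMs from MEME motif format or a plain probability table
#'
#' The plain table format is one `>motif_id [name]` header per motif
#' followed by one whitespace-separated row of four values (A C G U/T order)
#' per position; values may be counts or probabilities, both are
#' renormalized. Format `"auto"` sniffs for a `MEME version` header.
#'
#' @param content File path or character vector of lines.
#' @param format `"auto"`, `"meme"` or `"table"`.
#' @return A `pfm_set`.
#' @export
read_pfms <- function(content, format = c("auto", "meme", "table")) {
  format <- match.arg(format)
  lines <- read_text_lines(content)
  if (format == "auto") {
    format <- if (any(grepl("^MEME version", lines))) "meme" else "table"
  }
  if (format == "meme") parse_meme(lines) else parse_pfm_table(lines)
}

parse_meme <- function(lines) {
  starts <- grep("^MOTIF\\b", lines)
  if (length(starts) == 0L) abort("no MOTIF blocks found in MEME input")
  mats <- list(); nms <- character()
  for (i in seq_along(starts)) {
    hdr <- strsplit(trimws(lines[starts[i]]), "\\s+")[[1]]
    id <- hdr[2]
    nm <- if (length(hdr) >= 3) hdr[3] else id
    block_end <- if (i < length(starts)) starts[i + 1] - 1L else length(lines)
    block <- lines[(starts[i] + 1L):block_end]
    lp <- grep("letter-probability matrix", block)
    if (length(lp) == 0L) abort(sprintf("motif %s: missing letter-probability matrix", id))
    w <- as.integer(stringr::str_match(block[lp[1]], "w=\\s*(\\d+)")[, 2])
    rows <- block[(lp[1] + 1L):length(block)]
    rows <- rows[grepl("^\\s*[0-9.eE+-]", rows)]
    if (!is.na(w)) rows <- utils::head(rows, w)
    m <- do.call(rbind, lapply(rows, function(r) as.numeric(strsplit(trimws(r), "\\s+")[[1]])))
    mats[[id]] <- m
    nms <- c(nms, nm)
  }
  pfm_set(mats, names = nms)
}

parse_pfm_table <- function(lines) {
  lines <- lines[!grepl("^\\s*$", lines)]
  starts <- grep("^>", lines)
  if (length(starts) == 0L) abort("no '>motif_id' headers found in table input")
  mats <- list(); nms <- character()
  for (i in seq_along(starts)) {
    hdr <- strsplit(sub("^>\\s*", "", lines[starts[i]]), "\\s+")[[1]]
    id <- hdr[1]
    nm <- if (length(hdr) >= 2) hdr[2] else id
    block_end <- if (i < length(starts)) starts[i + 1] - 1L else length(lines)
    rows <- lines[(starts[i] + 1L):block_end]
    m <- do.call(rbind, lapply(rows, function(r) as.numeric(strsplit(trimws(r), "\\s+")[[1]])))
    mats[[id]] <- m
    nms <- c(nms, nm)
  }
  pfm_set(mats, names = nms)
}

#' Write a PFM set in MEME motif format
#'
#' @param pfms A `pfm_set`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_pfms <- function(pfms, file) {
  out <- c("MEME version 4", "", "ALPHABET= ACGT", "")
  for (i in seq_len(nrow(pfms))) {
    m <- pfms$pfm[[i]]
    out <- c(out,
             sprintf("MOTIF %s %s", pfms$motif_id[i], pfms$name[i]),
             sprintf("letter-probability matrix: alength= 4 w= %d", nrow(m)),
             apply(m, 1, function(r) paste(sprintf("%.6f", r), collapse = " ")),
             "")
  }
  readr::write_lines(out, file)
  invisible(file)
}

#' Consensus sequence of a PFM
#'
#' @param m A position-probability matrix (or `pfm_set` row's matrix).
#' @return Character consensus (most probable base per position, DNA
#'   alphabet).
#' @export
pfm_consensus <- function(m) {
  paste(PFM_BASES[apply(m, 1, which.max)], collapse = "")
}

# Random-sequence panel shared by similarity computations. Deterministic
# under the given seed so similarity is reproducible and symmetric.
similarity_panel <- function(n_seq = 500L, seq_len = 100L, panel_seed = 101L) {
  with_fixed_seed(panel_seed, {
    vapply(seq_len(n_seq),
           function(i) paste(sample(PFM_BASES, seq_len, replace = TRUE), collapse = ""),
           character(1))
  })
}

panel_affinities <- function(m, panel) {
  vapply(panel, function(s) scan_affinity(m, s)$affinity, numeric(1),
         USE.NAMES = FALSE)
}

#' Similarity of two PFMs via correlated affinity profiles
#'
#' Pearson correlation of the two motifs' affinity scores over a fixed panel
#' of random sequences (the energy-mode idea of affinity-based motif
#' comparison): near-identical motifs rank sequences identically and score
#' 1. Degenerate motifs with constant scores over the panel (e.g. the
#' uniform PFM) get similarity 0 with a `degenerate` attribute.
#'
#' @param a,b Position-probability matrices.
#' @param n_seq,seq_len Panel size and sequence length.
#' @param panel_seed Seed fixing the shared panel.
#' @return Similarity in \[-1, 1\]; attribute `degenerate` is TRUE when
#'   either profile is constant.
#' @export
pfm_similarity <- function(a, b, n_seq = 500L, seq_len = 100L, panel_seed = 101L) {
  panel <- similarity_panel(n_seq, seq_len, panel_seed)
  sa <- panel_affinities(a, panel)
  sb <- panel_affinities(b, panel)
  degenerate <- sd(sa) < 1e-12 || sd(sb) < 1e-12
  val <- if (degenerate) 0 else stats::cor(sa, sb)
  structure(val, degenerate = degenerate)
}

#' Pairwise PFM similarity matrix
#'
#' @param pfms A `pfm_set`.
#' @inheritParams pfm_similarity
#' @return Symmetric matrix of similarities (degenerate motifs score 0
#'   against everything, including themselves).
#' @export
pfm_similarity_matrix <- function(pfms, n_seq = 500L, seq_len = 100L,
                                  panel_seed = 101L) {
  panel <- similarity_panel(n_seq, seq_len, panel_seed)
  profiles <- vapply(pfms$pfm, panel_affinities, numeric(length(panel)), panel = panel)
  colnames(profiles) <- pfms$motif_id
  degen <- apply(profiles, 2, sd) < 1e-12
  sim <- suppressWarnings(stats::cor(profiles))
  sim[degen, ] <- 0
  sim[, degen] <- 0
  sim
}

#' Greedy clustering of PFMs into a non-redundant set
#'
#' Iterates motifs in input order; a motif joins the first existing cluster
#' whose representative (the cluster's first member) has similarity at or
#' above `threshold`, else it opens a new cluster. Deterministic given the
#' input order.
#'
#' @param pfms A `pfm_set`.
#' @param threshold Similarity required to join a cluster.
#' @param similarity Optional precomputed matrix from
#'   [pfm_similarity_matrix()].
#' @inheritParams pfm_similarity
#' @return List with `clusters` (tibble `motif_id`, `cluster`,
#'   `representative`) and `representatives` (the non-redundant `pfm_set`).
#' @export
cluster_pfms <- function(pfms, threshold = 0.75, similarity = NULL,
                         n_seq = 500L, seq_len = 100L, panel_seed = 101L) {
  sim <- similarity %||% pfm_similarity_matrix(pfms, n_seq, seq_len, panel_seed)
  ids <- pfms$motif_id
  reps <- character()
  assignment <- integer(length(ids))
  for (i in seq_along(ids)) {
    joined <- FALSE
    for (ci in seq_along(reps)) {
      if (sim[ids[i], reps[ci]] >= threshold) {
        assignment[i] <- ci
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      reps <- c(reps, ids[i])
      assignment[i] <- length(reps)
    }
  }
  clusters <- tibble(motif_id = ids, cluster = assignment,
                     representative = reps[assignment])
  list(clusters = clusters,
       representatives = pfms[match(reps, pfms$motif_id), ])
}
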