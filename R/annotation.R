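# annotation_build: partition a GTF into composite-exon and intron interval
# sets per gene. All internal coordinates are 0-based half-open [start, end);
# GTF and SAF are 1-based closed, converted at every I/O boundary.

GTF_EXONIC_TYPES <- c("exon", "UTR", "three_prime_utr", "five_prime_utr")

#' Parse a GTF into gene models
#'
#' Reads GENCODE-style GTF content (attribute dialect `key "value"; `) into a
#' `gene_models` object holding one gene span per `gene_id` plus all
#' per-transcript exon, UTR and CDS intervals. GTF 1-based closed coordinates
#' are converted to the internal 0-based half-open convention.
#'
#' Genes whose features span more than one chromosome or strand (annotation
#' artifacts) are dropped with a warning. An exon lying outside its gene's
#' declared span is a validation error.
#'
#' @param gtf Path to a GTF file, or a character vector of GTF lines (a
#'   single string containing newlines is also accepted).
#' @return An object of class `gene_models`: a list with
#'   * `genes`: tibble with `gene_id`, `chrom`, `start`, `end`, `strand`;
#'   * `features`: tibble with `gene_id`, `transcript_id`, `type`, `chrom`,
#'     `start`, `end`, `strand` for exon/UTR/CDS lines.
#' @examples
#' gtf <- c(
#'   "chr1\tx\tgene\t1\t300\t.\t+\t.\tgene_id \"g1\";",
#'   "chr1\tx\ttranscript\t1\t300\t.\t+\t.\tgene_id \"g1\"; transcript_id \"t1\";",
#'   "chr1\tx\texon\t1\t100\t.\t+\t.\tgene_id \"g1\"; transcript_id \"t1\";",
#'   "chr1\tx\texon\t201\t300\t.\t+\t.\tgene_id \"g1\"; transcript_id \"t1\";"
#' )
#' models <- parse_gtf(gtf)
#' build_composite_exons(models)
#' @export
parse_gtf <- function(gtf) {
  lines <- read_text_lines(gtf)
  keep <- !grepl("^\\s*(#|$)", lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    warn("GTF input contains no feature lines; returning empty gene models")
    return(new_gene_models(empty_genes_tbl(), empty_features_tbl()))
  }

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- line_no[which(nf != 9L)[1]]
    abort(sprintf("malformed GTF line %d: expected 9 tab-separated fields, found %d",
                  bad, nf[which(nf != 9L)[1]]))
  }
  fm <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  start <- suppressWarnings(as.integer(fm[, 4]))
  end <- suppressWarnings(as.integer(fm[, 5]))
  bad_coord <- which(is.na(start) | is.na(end))
  if (length(bad_coord)) {
    abort(sprintf("malformed GTF line %d: non-integer coordinates '%s', '%s'",
                  line_no[bad_coord[1]], fm[bad_coord[1], 4], fm[bad_coord[1], 5]))
  }
  bad_order <- which(end < start)
  if (length(bad_order)) {
    abort(sprintf("malformed GTF line %d: end (%d) < start (%d)",
                  line_no[bad_order[1]], end[bad_order[1]], start[bad_order[1]]))
  }

  tbl <- tibble(
    chrom = fm[, 1], type = fm[, 3],
    start = start - 1L, end = end,  # to 0-based half-open
    strand = fm[, 7],
    gene_id = gtf_attribute(fm[, 9], "gene_id"),
    transcript_id = gtf_attribute(fm[, 9], "transcript_id"),
    line = line_no
  )
  no_gene <- which(is.na(tbl$gene_id))
  if (length(no_gene)) {
    abort(sprintf("malformed GTF line %d: missing gene_id attribute", tbl$line[no_gene[1]]))
  }
  bad_strand <- which(!tbl$strand %in% c("+", "-"))
  if (length(bad_strand)) {
    abort(sprintf("malformed GTF line %d: strand must be '+' or '-'", tbl$line[bad_strand[1]]))
  }

  feats <- tbl |>
    filter(.data$type %in% c(GTF_EXONIC_TYPES, "CDS")) |>
    select("gene_id", "transcript_id", "type", "chrom", "start", "end", "strand")

  gene_lines <- tbl |> filter(.data$type == "gene")
  if (nrow(gene_lines)) {
    genes <- gene_lines |>
      select("gene_id", "chrom", "start", "end", "strand") |>
      distinct()
  } else {
    # no explicit gene lines: derive spans from the features themselves
    genes <- feats |>
      group_by(.data$gene_id, .data$chrom, .data$strand) |>
      summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") |>
      select("gene_id", "chrom", "start", "end", "strand")
  }

  # drop genes split across chromosomes or strands
  placement <- bind_rows(
    genes |> select("gene_id", "chrom", "strand"),
    feats |> select("gene_id", "chrom", "strand")
  ) |> distinct()
  multi <- placement |> dplyr::count(.data$gene_id) |> filter(.data$n > 1L)
  if (nrow(multi)) {
    warn(sprintf("dropping %d gene(s) with features on multiple chromosomes/strands: %s",
                 nrow(multi), paste(multi$gene_id, collapse = ", ")))
    genes <- genes |> filter(!.data$gene_id %in% multi$gene_id)
    feats <- feats |> filter(!.data$gene_id %in% multi$gene_id)
  }

  # every feature must lie within its gene span
  chk <- feats |>
    inner_join(genes |> rename(g_start = "start", g_end = "end"),
               by = c("gene_id", "chrom", "strand"))
  out_of_span <- chk |> filter(.data$start < .data$g_start | .data$end > .data$g_end)
  if (nrow(out_of_span)) {
    abort(sprintf("validation error: %s feature [%d, %d) of gene %s lies outside its gene span",
                  out_of_span$type[1], out_of_span$start[1], out_of_span$end[1],
                  out_of_span$gene_id[1]))
  }

  new_gene_models(genes |> arrange(.data$gene_id), feats)
}

new_gene_models <- function(genes, features) {
  structure(list(genes = genes, features = features), class = "gene_models")
}

empty_genes_tbl <- function() {
  tibble(gene_id = character(), chrom = character(), start = integer(),
         end = integer(), strand = character())
}

empty_features_tbl <- function() {
  tibble(gene_id = character(), transcript_id = character(), type = character(),
         chrom = character(), start = integer(), end = integer(), strand = character())
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("<gene_models> %d gene(s), %d feature interval(s)\n",
              nrow(x$genes), nrow(x$features)))
  invisible(x)
}

read_text_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    return(readr::read_lines(x))
  }
  unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
}

gtf_attribute <- function(attrs, key) {
  m <- stringr::str_match(attrs, paste0('(?:^|;)\\s*', key, '\\s+"([^"]*)"'))
  m[, 2]
}

# Merge possibly-overlapping intervals of one gene into disjoint sorted ones.
reduce_intervals <- function(start, end) {
  ir <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
  tibble(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

# Subtract intervals `sub` from intervals `from` (both 0-based half-open).
subtract_intervals <- function(from, sub) {
  a <- IRanges::IRanges(start = from$start + 1L, end = from$end)
  b <- IRanges::IRanges(start = sub$start + 1L, end = sub$end)
  d <- IRanges::setdiff(a, b)
  tibble(start = IRanges::start(d) - 1L, end = IRanges::end(d))
}

#' Composite exons: merged union of exon and UTR intervals across isoforms
#'
#' For every gene, takes the union of all exon and UTR intervals over all of
#' its transcripts and merges them into disjoint, sorted intervals.
#'
#' @param models A `gene_models` object from [parse_gtf()].
#' @return Tibble with `gene_id`, `chrom`, `start`, `end`, `strand`
#'   (0-based half-open, disjoint, sorted within gene).
#' @export
build_composite_exons <- function(models) {
  stopifnot(inherits(models, "gene_models"))
  feats <- models$features |> filter(.data$type %in% GTF_EXONIC_TYPES)
  missing <- setdiff(models$genes$gene_id, feats$gene_id)
  if (length(missing)) {
    warn(sprintf("%d gene(s) have no exon/UTR features and get empty composite exons: %s",
                 length(missing), paste(missing, collapse = ", ")))
  }
  if (nrow(feats) == 0L) {
    return(tibble(gene_id = character(), chrom = character(), start = integer(),
                  end = integer(), strand = character()))
  }
  feats |>
    group_by(.data$gene_id, .data$chrom, .data$strand) |>
    dplyr::reframe(reduce_intervals(.data$start, .data$end)) |>
    select("gene_id", "chrom", "start", "end", "strand") |>
    arrange(.data$gene_id, .data$start)
}

#' Introns: gene span minus composite exons
#'
#' The intronic interval set of a gene is its span minus its composite exons.
#' With `mask_cross_gene = TRUE`, intron bases overlapping any same-strand
#' composite exon of *another* gene are additionally removed (contamination
#' control for overlapping genes); the default reproduces the plain per-gene
#' subtraction.
#'
#' @param models A `gene_models` object.
#' @param composite Composite exon tibble from [build_composite_exons()];
#'   recomputed when `NULL`.
#' @param mask_cross_gene Mask intron bases covered by other genes'
#'   same-strand composite exons.
#' @return Tibble with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
build_introns <- function(models, composite = NULL, mask_cross_gene = FALSE) {
  stopifnot(inherits(models, "gene_models"))
  composite <- composite %||% suppressWarnings(build_composite_exons(models))
  comp_by_gene <- split(composite, composite$gene_id)
  rows <- purrr::pmap(models$genes, function(gene_id, chrom, start, end, strand) {
    span <- tibble(start = start, end = end)
    comp <- comp_by_gene[[gene_id]]
    introns <- if (is.null(comp)) span else subtract_intervals(span, comp)
    if (mask_cross_gene && nrow(introns)) {
      other <- composite |>
        filter(.data$gene_id != !!gene_id, .data$chrom == !!chrom,
               .data$strand == !!strand)
      if (nrow(other)) introns <- subtract_intervals(introns, other)
    }
    if (nrow(introns) == 0L) return(NULL)
    tibble(gene_id = gene_id, chrom = chrom, start = introns$start,
           end = introns$end, strand = strand)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble(gene_id = character(), chrom = character(), start = integer(),
                  end = integer(), strand = character()))
  }
  arrange(out, .data$gene_id, .data$start)
}

#' Build the full annotation set for external read counters
#'
#' Convenience wrapper producing composite exons, introns and per-gene
#' composite exon lengths in one pass.
#'
#' @inheritParams build_introns
#' @return An `annotation_set`: list with `composite_exons`, `introns`
#'   (interval tibbles) and `exon_lengths` (tibble `gene_id`, `exon_length`).
#' @export
build_annotation <- function(models, mask_cross_gene = FALSE) {
  composite <- build_composite_exons(models)
  introns <- build_introns(models, composite, mask_cross_gene = mask_cross_gene)
  lengths <- composite |>
    group_by(.data$gene_id) |>
    summarise(exon_length = sum(.data$end - .data$start), .groups = "drop")
  structure(list(composite_exons = composite, introns = introns,
                 exon_lengths = lengths, genes = models$genes),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d gene(s): %d composite exon(s), %d intron(s)\n",
              nrow(x$exon_lengths), nrow(x$composite_exons), nrow(x$introns)))
  invisible(x)
}

#' Write an interval set as GTF or SAF
#'
#' Converts internal 0-based half-open intervals back to the 1-based closed
#' convention of both dialects. The GTF dialect writes one `gene` line per
#' gene plus one `exon` line per interval and is round-trip safe through
#' [parse_gtf()]; the SAF dialect writes the `GeneID Chr Start End Strand`
#' TSV consumed by featureCounts-style counters and round-trips through
#' [read_saf()].
#'
#' @param intervals Interval tibble (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`) such as from [build_composite_exons()] or [build_introns()].
#' @param file Output path.
#' @param dialect `"gtf"` or `"saf"`.
#' @param feature GTF feature type to write interval lines as.
#' @return `file`, invisibly.
#' @export
write_annotation <- function(intervals, file, dialect = c("gtf", "saf"),
                             feature = "exon") {
  dialect <- match.arg(dialect)
  iv <- arrange(as_tibble(intervals), .data$gene_id, .data$start)
  if (dialect == "saf") {
    header <- "GeneID\tChr\tStart\tEnd\tStrand"
    body <- sprintf("%s\t%s\t%d\t%d\t%s", iv$gene_id, iv$chrom,
                    iv$start + 1L, iv$end, iv$strand)
    readr::write_lines(c(header, body), file)
    return(invisible(file))
  }
  spans <- iv |>
    group_by(.data$gene_id, .data$chrom, .data$strand) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  gene_lines <- sprintf('%s\tintrodelta\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
                        spans$chrom, spans$start + 1L, spans$end, spans$strand,
                        spans$gene_id)
  feat_lines <- sprintf('%s\tintrodelta\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
                        iv$chrom, feature, iv$start + 1L, iv$end, iv$strand,
                        iv$gene_id, iv$gene_id)
  readr::write_lines(c("## introdelta annotation", gene_lines, feat_lines), file)
  invisible(file)
}

#' Read a SAF annotation table back into internal coordinates
#'
#' @param file SAF file written by [write_annotation()] (or featureCounts
#'   conventions: `GeneID`, `Chr`, `Start`, `End`, `Strand`, 1-based closed).
#' @return Interval tibble in the internal 0-based half-open convention.
#' @export
read_saf <- function(file) {
  tbl <- readr::read_tsv(file, show_col_types = FALSE)
  names(tbl) <- tolower(names(tbl))
  tibble(gene_id = as.character(tbl$geneid), chrom = as.character(tbl$chr),
         start = as.integer(tbl$start) - 1L, end = as.integer(tbl$end),
         strand = as.character(tbl$strand))
}

#' Flag genes whose isoforms share a single 3'UTR start
#'
#' Alternative splicing confounds 3'UTR motif analysis; downstream motif
#' scanning therefore restricts to genes whose transcripts all begin their
#' 3'UTR at the same coordinate. The 3'UTR start of a transcript is taken
#' from its CDS end when CDS features are present (the base after the coding
#' region, strand-aware), else from explicit `three_prime_utr` features.
#' Transcripts providing neither are uninformative and make the gene
#' ineligible.
#'
#' @param models A `gene_models` object.
#' @return Tibble with `gene_id`, `utr3_start` (NA when inconsistent or
#'   unknown) and logical `eligible`.
#' @export
utr_eligibility <- function(models) {
  stopifnot(inherits(models, "gene_models"))
  feats <- models$features
  utr3_from <- function(df, plus_fun, minus_fun) {
    if (nrow(df) == 0L) {
      return(tibble(gene_id = character(), transcript_id = character(),
                    utr3_start = integer()))
    }
    df |>
      group_by(.data$gene_id, .data$transcript_id, .data$strand) |>
      summarise(utr3_start = if (.data$strand[1] == "+") plus_fun(.data$start, .data$end)
                else minus_fun(.data$start, .data$end),
                .groups = "drop") |>
      select("gene_id", "transcript_id", "utr3_start")
  }
  tx_cds <- utr3_from(filter(feats, .data$type == "CDS", !is.na(.data$transcript_id)),
                      function(s, e) max(e), function(s, e) min(s))
  tx_utr3 <- utr3_from(filter(feats, .data$type == "three_prime_utr",
                              !is.na(.data$transcript_id)),
                       function(s, e) min(s), function(s, e) max(e))
  tx <- bind_rows(tx_cds, dplyr::anti_join(tx_utr3, tx_cds,
                                           by = c("gene_id", "transcript_id")))
  all_tx <- feats |>
    filter(!is.na(.data$transcript_id)) |>
    distinct(.data$gene_id, .data$transcript_id)
  per_gene <- all_tx |>
    left_join(tx |> select("gene_id", "transcript_id", "utr3_start"),
              by = c("gene_id", "transcript_id")) |>
    group_by(.data$gene_id) |>
    summarise(
      eligible = !anyNA(.data$utr3_start) && dplyr::n_distinct(.data$utr3_start) == 1L,
      first_start = .data$utr3_start[1],
      .groups = "drop"
    ) |>
    mutate(utr3_start = dplyr::if_else(.data$eligible, as.integer(.data$first_start),
                                       NA_integer_)) |>
    select("gene_id", "utr3_start", "eligible")
  models$genes |>
    select("gene_id") |>
    left_join(per_gene, by = "gene_id") |>
    mutate(eligible = !is.na(.data$eligible) & .data$eligible) |>
    select("gene_id", "utr3_start", "eligible")
}
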