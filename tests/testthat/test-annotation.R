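# GTF parsing, composite-exon union, intron complement, dialect round trips.

toy_gtf <- c(
  'chr1\tsim\tgene\t1\t300\t.\t+\t.\tgene_id "g1";',
  'chr1\tsim\ttranscript\t1\t300\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
  'chr1\tsim\texon\t1\t100\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
  'chr1\tsim\texon\t151\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
  'chr1\tsim\ttranscript\t41\t300\t.\t+\t.\tgene_id "g1"; transcript_id "t2";',
  'chr1\tsim\texon\t41\t160\t.\t+\t.\tgene_id "g1"; transcript_id "t2";'
)

test_that("parse_gtf reads features back verbatim with 0-based half-open coords", {
  models <- parse_gtf(toy_gtf)
  expect_s3_class(models, "gene_models")
  expect_equal(nrow(models$genes), 1L)
  expect_equal(models$genes$start, 0L)
  expect_equal(models$genes$end, 300L)
  ex <- dplyr::filter(models$features, type == "exon")
  expect_equal(nrow(ex), 3L)
  expect_equal(sort(unique(ex$transcript_id)), c("t1", "t2"))
  # GTF "1 100" -> [0, 100)
  expect_equal(ex$start[1], 0L)
  expect_equal(ex$end[1], 100L)
})

test_that("parse_gtf handles empty and malformed input", {
  expect_warning(m <- parse_gtf(character()), "no feature lines")
  expect_equal(nrow(m$genes), 0L)
  expect_error(parse_gtf("chr1\tx\texon\t1\t100"), "line 1.*9 tab")
  expect_error(parse_gtf('chr1\tx\texon\tA\t100\t.\t+\t.\tgene_id "g";'),
               "line 1.*non-integer")
  bad <- c(toy_gtf, 'chr1\tsim\texon\t500\t400\t.\t+\t.\tgene_id "g1"; transcript_id "t1";')
  expect_error(parse_gtf(bad), "line 7.*end")
  out <- c(toy_gtf, 'chr1\tsim\texon\t900\t1000\t.\t+\t.\tgene_id "g1"; transcript_id "t1";')
  expect_error(parse_gtf(out), "outside its gene span")
})

test_that("genes split across chromosomes or strands are dropped with a warning", {
  split_gene <- c(
    toy_gtf,
    'chr2\tsim\texon\t10\t50\t.\t+\t.\tgene_id "g2"; transcript_id "t3";',
    'chr3\tsim\texon\t10\t50\t.\t+\t.\tgene_id "g2"; transcript_id "t4";'
  )
  expect_warning(models <- parse_gtf(split_gene), "multiple chromosomes")
  expect_false("g2" %in% models$genes$gene_id)
  expect_true("g1" %in% models$genes$gene_id)
})

test_that("composite exons merge overlapping intervals and are idempotent", {
  models <- parse_gtf(toy_gtf)
  comp <- build_composite_exons(models)
  # [0,100) u [150,200) u [40,160) = [0,200)
  expect_equal(comp$start, 0L)
  expect_equal(comp$end, 200L)
  expect_equal(comp$strand, "+")
  # already-disjoint intervals pass through unchanged
  gtf2 <- c('chr1\ts\tgene\t1\t400\t.\t-\t.\tgene_id "g";',
            'chr1\ts\texon\t1\t100\t.\t-\t.\tgene_id "g"; transcript_id "t";',
            'chr1\ts\texon\t201\t400\t.\t-\t.\tgene_id "g"; transcript_id "t";')
  comp2 <- build_composite_exons(parse_gtf(gtf2))
  expect_equal(comp2$start, c(0L, 200L))
  expect_equal(comp2$end, c(100L, 400L))
  expect_equal(comp2$strand, c("-", "-"))
})

test_that("introns are the span complement; single-exon gene has none", {
  models <- parse_gtf(toy_gtf)
  introns <- build_introns(models)
  expect_equal(introns$start, 200L)
  expect_equal(introns$end, 300L)
  single <- c('chr1\ts\tgene\t1\t100\t.\t+\t.\tgene_id "g";',
              'chr1\ts\texon\t1\t100\t.\t+\t.\tgene_id "g"; transcript_id "t";')
  expect_equal(nrow(build_introns(parse_gtf(single))), 0L)
})

test_that("composite union and intron complement match per-base oracles on random toy genes", {
  withr::with_seed(71, {
    for (rep in 1:8) {
      tg <- random_toy_gene(sprintf("g%d", rep))
      models <- parse_gtf(tg$gtf)
      comp <- build_composite_exons(models)
      introns <- build_introns(models, comp)
      span <- tg$span
      cov_true <- perbase_coverage(tg$exons$start, tg$exons$end, span[1], span[2])
      cov_comp <- perbase_coverage(comp$start, comp$end, span[1], span[2])
      cov_intr <- perbase_coverage(introns$start, introns$end, span[1], span[2])
      expect_identical(cov_comp, cov_true)
      expect_identical(cov_intr, !cov_true)
      # partition invariant: disjoint, union covers the whole span
      expect_false(any(cov_comp & cov_intr))
      expect_true(all(cov_comp | cov_intr))
    }
  })
})

test_that("cross-gene masking removes intron bases under another gene's exons", {
  gtf <- c(
    'chr1\ts\tgene\t1\t1000\t.\t+\t.\tgene_id "gA";',
    'chr1\ts\texon\t1\t100\t.\t+\t.\tgene_id "gA"; transcript_id "tA";',
    'chr1\ts\texon\t901\t1000\t.\t+\t.\tgene_id "gA"; transcript_id "tA";',
    'chr1\ts\tgene\t301\t500\t.\t+\t.\tgene_id "gB";',
    'chr1\ts\texon\t301\t500\t.\t+\t.\tgene_id "gB"; transcript_id "tB";'
  )
  models <- parse_gtf(gtf)
  plain <- build_introns(models)
  masked <- build_introns(models, mask_cross_gene = TRUE)
  gA_plain <- dplyr::filter(plain, gene_id == "gA")
  gA_masked <- dplyr::filter(masked, gene_id == "gA")
  expect_equal(gA_plain$start, 100L)
  expect_equal(gA_plain$end, 900L)
  expect_equal(gA_masked$start, c(100L, 500L))
  expect_equal(gA_masked$end, c(300L, 900L))
})

test_that("GTF and SAF writers round-trip and use 1-based closed coordinates", {
  models <- parse_gtf(toy_gtf)
  ann <- build_annotation(models)
  gtf_file <- withr::local_tempfile(fileext = ".gtf")
  write_annotation(ann$composite_exons, gtf_file, "gtf")
  reread <- build_composite_exons(parse_gtf(gtf_file))
  expect_equal(reread$start, ann$composite_exons$start)
  expect_equal(reread$end, ann$composite_exons$end)
  # [100, 200) internal -> "101 200" on disk
  iv <- tibble::tibble(gene_id = "g", chrom = "chr1", start = 100L, end = 200L,
                       strand = "+")
  f2 <- withr::local_tempfile(fileext = ".gtf")
  write_annotation(iv, f2, "gtf")
  line <- grep("\texon\t", readLines(f2), value = TRUE)
  expect_match(line, "\t101\t200\t")
  saf_file <- withr::local_tempfile(fileext = ".saf")
  write_annotation(ann$introns, saf_file, "saf")
  back <- read_saf(saf_file)
  expect_equal(back$start, ann$introns$start)
  expect_equal(back$end, ann$introns$end)
  # header-only file for an empty set
  f3 <- withr::local_tempfile(fileext = ".saf")
  write_annotation(ann$introns[0, ], f3, "saf")
  expect_equal(readLines(f3), "GeneID\tChr\tStart\tEnd\tStrand")
  expect_error(write_annotation(ann$introns, f3, "bed"), "arg")
})

test_that("exon lengths sum composite widths and 3'UTR eligibility uses CDS ends", {
  models <- parse_gtf(toy_gtf)
  ann <- build_annotation(models)
  expect_equal(ann$exon_lengths$exon_length, 200L)
  gtf <- c(
    'chr1\ts\tgene\t1\t500\t.\t+\t.\tgene_id "gE";',
    'chr1\ts\tCDS\t1\t200\t.\t+\t.\tgene_id "gE"; transcript_id "t1";',
    'chr1\ts\texon\t1\t300\t.\t+\t.\tgene_id "gE"; transcript_id "t1";',
    'chr1\ts\tCDS\t1\t200\t.\t+\t.\tgene_id "gE"; transcript_id "t2";',
    'chr1\ts\texon\t1\t500\t.\t+\t.\tgene_id "gE"; transcript_id "t2";',
    'chr1\ts\tgene\t1\t500\t.\t+\t.\tgene_id "gI";',
    'chr1\ts\tCDS\t1\t200\t.\t+\t.\tgene_id "gI"; transcript_id "t3";',
    'chr1\ts\texon\t1\t300\t.\t+\t.\tgene_id "gI"; transcript_id "t3";',
    'chr1\ts\tCDS\t1\t250\t.\t+\t.\tgene_id "gI"; transcript_id "t4";',
    'chr1\ts\texon\t1\t500\t.\t+\t.\tgene_id "gI"; transcript_id "t4";'
  )
  elig <- utr_eligibility(parse_gtf(gtf))
  expect_true(elig$eligible[elig$gene_id == "gE"])
  expect_false(elig$eligible[elig$gene_id == "gI"])
  expect_equal(elig$utr3_start[elig$gene_id == "gE"], 200L)
})
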