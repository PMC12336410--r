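# PFM I/O, similarity and clustering, affinity scanning, k-mer and seed
# matching, Fisher enrichment.

uniform_pfm <- matrix(0.25, 4, 4)

test_that("PFM readers normalize probabilities and round-trip through MEME", {
  meme <- c("MEME version 4", "", "ALPHABET= ACGT", "",
            "MOTIF u1 uniform",
            "letter-probability matrix: alength= 4 w= 4",
            rep("0.25 0.25 0.25 0.25", 4))
  pf <- read_pfms(meme)
  expect_equal(pf$motif_id, "u1")
  expect_equal(pf$pfm[[1]], matrix(0.25, 4, 4, dimnames = list(NULL, c("A","C","G","T"))))
  # counts in the plain table are normalized to probabilities
  tab <- c(">m counts", "2 0 0 2", "0 4 0 0", "1 1 1 1")
  pt <- read_pfms(tab, format = "table")
  expect_true(all(abs(rowSums(pt$pfm[[1]]) - 1) < 1e-6))
  expect_true(all(pt$pfm[[1]] >= 1e-3 / 2))  # zero cells floored
  # round trip
  pfms <- random_pfms(4, seed = 2)
  f <- withr::local_tempfile(fileext = ".meme")
  write_pfms(pfms, f)
  back <- read_pfms(f)
  expect_equal(back$motif_id, pfms$motif_id)
  for (i in 1:4) expect_lt(max(abs(back$pfm[[i]] - pfms$pfm[[i]])), 1e-5)
  # zero-sum position is an error naming motif and position
  expect_error(read_pfms(c(">bad", "1 0 0 0", "0 0 0 0", "1 0 0 0"), "table"),
               "bad.*position 2")
})

test_that("pfm_similarity is symmetric, 1 for identical motifs, 0 for degenerate", {
  pfms <- random_pfms(3, seed = 4)
  a <- pfms$pfm[[1]]; b <- pfms$pfm[[2]]
  expect_equal(as.numeric(pfm_similarity(a, a)), 1, tolerance = 1e-12)
  sab <- pfm_similarity(a, b)
  sba <- pfm_similarity(b, a)
  expect_equal(as.numeric(sab), as.numeric(sba), tolerance = 1e-12)
  u <- pfm_similarity(uniform_pfm, a)
  expect_equal(as.numeric(u), 0)
  expect_true(attr(u, "degenerate"))
  # equals direct correlation of independently recomputed score vectors
  panel <- withr::with_seed(101, {
    vapply(1:500, function(i) paste(sample(c("A","C","G","T"), 100, TRUE),
                                    collapse = ""), character(1))
  })
  va <- vapply(panel, function(s) scan_oracle(a, s)$affinity, numeric(1))
  vb <- vapply(panel, function(s) scan_oracle(b, s)$affinity, numeric(1))
  expect_equal(as.numeric(sab), cor(va, vb), tolerance = 1e-9)
})

test_that("greedy clustering matches a hand-run trace and handles edge thresholds", {
  pfms <- random_pfms(6, seed = 9)
  # plant two near-identical pairs: m05 ~ m01, m06 ~ m02
  pfms$pfm[[5]] <- pfms$pfm[[1]]
  pfms$pfm[[6]] <- pfms$pfm[[2]]
  cl <- cluster_pfms(pfms, threshold = 0.95)
  cls <- cl$clusters
  expect_equal(cls$cluster[cls$motif_id == "m05"], cls$cluster[cls$motif_id == "m01"])
  expect_equal(cls$cluster[cls$motif_id == "m06"], cls$cluster[cls$motif_id == "m02"])
  expect_equal(cls$representative[cls$motif_id == "m05"], "m01")
  # hand-run greedy trace on the same similarity matrix
  sim <- pfm_similarity_matrix(pfms)
  reps <- character(); assign <- integer(6)
  for (i in 1:6) {
    hit <- which(vapply(reps, function(r) sim[pfms$motif_id[i], r] >= 0.95, logical(1)))
    if (length(hit)) assign[i] <- hit[1]
    else { reps <- c(reps, pfms$motif_id[i]); assign[i] <- length(reps) }
  }
  expect_equal(cls$cluster, assign)
  # threshold above 1: every motif is its own cluster
  singletons <- cluster_pfms(pfms, threshold = 1.01, similarity = sim)
  expect_equal(nrow(singletons$representatives), 6L)
  # duplicated motif list merges into singleton clusters
  dup <- pfm_set(setNames(list(pfms$pfm[[1]], pfms$pfm[[1]], pfms$pfm[[1]]),
                          c("a", "b", "c")))
  cl_dup <- cluster_pfms(dup, threshold = 0.99)
  expect_equal(nrow(cl_dup$representatives), 1L)
})

test_that("scan_affinity equals the window-enumeration oracle and calls presence", {
  withr::with_seed(61, {
    pfms <- random_pfms(3, seed = 12)
    seqs <- vapply(1:5, function(i) paste(sample(c("A","C","G","T"), 60, TRUE),
                                          collapse = ""), character(1))
    for (m in pfms$pfm) {
      for (s in seqs) {
        got <- scan_affinity(m, s)
        want <- scan_oracle(m, s)
        expect_equal(got$affinity, want$affinity, tolerance = 1e-9)
        expect_equal(got$best_score, want$best, tolerance = 1e-12)
      }
    }
  })
  # a consensus (certainty) motif present in the sequence: best window = max attainable
  cons <- matrix(1e-9, 5, 4); cons[cbind(1:5, c(1, 2, 3, 4, 1))] <- 1
  cons <- cons / rowSums(cons)
  hit <- scan_affinity(cons, "TTACGTATT")
  expect_true(hit$presence)
  expect_equal(hit$best_start, 2L)
  expect_equal(hit$best_score, hit$max_attainable, tolerance = 1e-6)
  # sequence shorter than the motif
  short <- scan_affinity(cons, "ACG")
  expect_equal(short$affinity, 0)
  expect_false(short$presence)
  expect_equal(short$flag, "short_seq")
  # RNA alphabet equals DNA alphabet
  expect_equal(scan_affinity(cons, "UUACGUAUU")$affinity, hit$affinity)
  # non-alphabet characters warn and zero their windows
  expect_warning(nn <- scan_affinity(cons, "NNNNNNNNN"), "non-ACGTU")
  expect_equal(suppressWarnings(scan_affinity(cons, "NNNNNNNNN")$flag),
               "no_scorable_window")
})

test_that("planted consensi rank above random UTRs in affinity", {
  pfms <- random_pfms(1, seed = 33)
  genes <- sprintf("g%03d", 1:200)
  planted <- setNames(rep("m01", 100), genes[1:100])
  su <- simulate_utrs(genes, planted = planted, pfms = pfms, seed = 34)
  bm <- scan_motifs(su$utrs, pfms)
  aff <- bm$affinity$m01
  ranked <- mean(outer(aff[1:100], aff[101:200], ">"))
  expect_gte(ranked, 0.95)
})

test_that("kmer_sites counts overlapping IUPAC matches with 0-based coordinates", {
  hits <- kmer_sites("AAA", "AAAAA")
  expect_equal(nrow(hits), 3L)
  expect_equal(hits$start, 0:2)
  one <- kmer_sites("ATTTA", "GGATTTAGG")
  expect_equal(nrow(one), 1L)
  expect_equal(one$start, 2L)
  expect_equal(nrow(kmer_sites("ATTTA", "GGGGGG")), 0L)
  # RNA input and IUPAC ambiguity
  expect_equal(nrow(kmer_sites("AUUUA", "GGAUUUAGG")), 1L)
  expect_equal(nrow(kmer_sites("ARA", "AGAACA")), 1L)  # R = A/G only
  expect_equal(kmer_sites("ARA", "AGAAAA")$start, c(0L, 2L, 3L))
  expect_error(kmer_sites("AX!", "ACGT"), "invalid IUPAC")
  expect_error(kmer_sites("", "ACGT"), "non-empty")
})

test_that("miRNA seed patterns are reverse complements of the seed region", {
  mir9 <- "UCUUUGGUUAUCUAGCUGUAUGA"
  expect_equal(mirna_seed_pattern(mir9, "7mer-m8"), "ACCAAAG")
  expect_equal(mirna_seed_pattern(mir9, "8mer"), "ACCAAAGA")
  expect_equal(mirna_seed_pattern(mir9, "7mer-A1"), "CCAAAGA")
})

test_that("enrichment_test matches the hypergeometric tail and handles edge tables", {
  flat <- enrichment_test(10, 20, 20, 40)
  expect_equal(flat$odds_ratio, 1)
  expect_equal(flat$p, stats::fisher.test(matrix(c(10, 10, 10, 10), 2),
                                          alternative = "greater")$p.value)
  # all hits inside the set: p equals the direct hypergeometric sum
  conc <- enrichment_test(5, 10, 5, 100)
  expect_equal(conc$p, hyper_tail_oracle(5, 10, 5, 100), tolerance = 1e-12)
  expect_true(conc$haldane)  # a zero cell triggers the 0.5 correction
  expect_true(is.finite(conc$odds_ratio))
  withr::with_seed(77, {
    for (i in 1:10) {
      uni <- sample(50:200, 1); set <- sample(5:30, 1)
      hits <- sample(5:40, 1); a <- sample(0:min(set, hits), 1)
      expect_equal(enrichment_test(a, set, hits, uni)$p,
                   hyper_tail_oracle(a, set, hits, uni), tolerance = 1e-9)
    }
  })
  expect_error(enrichment_test(0, 0, 5, 100), "empty")
  expect_error(enrichment_test(0, 5, 5, 0), "positive")
})
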