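# Median centering, robust slope fits, the slope-contrast test, ratio,
# per-individual scores, DPRG calling, and whole-fit invariances.

test_that("median_center subtracts the per-gene reference median", {
  expr <- tibble::tibble(gene_id = c("a", "b"),
                         s1 = c(1, 5), s2 = c(2, 5), s3 = c(3, 5),
                         s4 = c(4, 5), s5 = c(10, 5))
  out <- median_center(expr)
  expect_equal(unlist(out[1, -1], use.names = FALSE), c(-2, -1, 0, 1, 7))
  expect_equal(unlist(out[2, -1], use.names = FALSE), rep(0, 5))
  # odd-sized reference: the median is a datum, so one exact zero per gene
  expect_true(any(unlist(out[1, -1]) == 0))
  # control-only reference
  out_c <- median_center(expr, reference = c("s1", "s2", "s3"))
  expect_equal(unlist(out_c[1, -1], use.names = FALSE), c(-1, 0, 1, 2, 8))
  expect_error(median_center(expr, reference = character()), "empty")
  expect_error(median_center(expr, reference = "nope"), "not in matrix")
})

test_that("huber_line recovers an exact line and resists gross outliers", {
  withr::with_seed(51, {
    x <- rnorm(30)
    y <- 1.3 * x
    fit <- huber_line(x, y)
    expect_equal(fit$slope, 1.3, tolerance = 1e-8)
    expect_lt(fit$se, 1e-6)
    expect_true(fit$converged)
    # two gross outliers
    y2 <- y
    y2[c(3, 17)] <- y2[c(3, 17)] + 10
    rob <- huber_line(x, y2)
    ols <- coef(lm(y2 ~ x))[2]
    expect_lt(abs(rob$slope - 1.3), 0.05)
    expect_lt(abs(rob$slope - 1.3), abs(ols - 1.3))
  })
})

test_that("huber_line agrees with MASS::rlm on noisy data", {
  skip_if_not_installed("MASS")
  withr::with_seed(52, {
    x <- rnorm(200)
    y <- 0.8 * x + rt(200, df = 3) * 0.5
    ours <- huber_line(x, y)
    theirs <- MASS::rlm(y ~ x, psi = MASS::psi.huber, k = 1.345, maxit = 50)
    expect_equal(ours$slope, unname(coef(theirs)[2]), tolerance = 1e-3)
  })
})

test_that("fit_group_slope gates on sample size and degenerate predictors", {
  fit <- fit_group_slope(c(1, 2, 3), c(1, 2, 3), min_fit_n = 10)
  expect_true(fit$skipped)
  expect_match(fit$reason, "below min_fit_n")
  same <- fit_group_slope(rep(1, 20), rnorm(20))
  expect_true(same$skipped)
  expect_match(same$reason, "degenerate")
  ok <- fit_group_slope(rnorm(20), rnorm(20))
  expect_false(ok$skipped)
  expect_gte(ok$se, 0)
})

test_that("delta_ptgr_test reproduces the printed formula and its symmetries", {
  fit_d <- tibble::tibble(slope = 1.5, se = 0.1, n = 50L)
  fit_c <- tibble::tibble(slope = 1.0, se = 0.1, n = 50L)
  res <- delta_ptgr_test(fit_d, fit_c)
  expect_equal(res$t, 0.5 / sqrt(0.02), tolerance = 1e-12)
  expect_equal(res$t, 3.53553, tolerance = 1e-5)
  expect_equal(res$df, 100L)
  expect_equal(res$p, 2 * pt(res$t, 100, lower.tail = FALSE))
  # equal slopes: t = 0, p = 1
  eq <- delta_ptgr_test(fit_c, fit_c)
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
  # antisymmetry under swapping the fits
  swapped <- delta_ptgr_test(fit_c, fit_d)
  expect_equal(swapped$t, -res$t)
  expect_equal(swapped$p, res$p)
  # degenerate zero-SE cases
  z_eq <- delta_ptgr_test(tibble::tibble(slope = 1, se = 0, n = 10),
                          tibble::tibble(slope = 1, se = 0, n = 10))
  expect_equal(z_eq$t, 0); expect_equal(z_eq$p, 1)
  expect_false(z_eq$exact_separation)
  z_ne <- delta_ptgr_test(tibble::tibble(slope = 2, se = 0, n = 10),
                          tibble::tibble(slope = 1, se = 0, n = 10))
  expect_equal(z_ne$p, 0)
  expect_true(z_ne$exact_separation)
  # welch df is smaller than the printed df but positive
  w <- delta_ptgr_test(fit_d, fit_c, df_mode = "welch")
  expect_lt(w$df, 100)
  expect_gt(w$df, 0)
})

test_that("ptgr_ratio evaluates |slope_D/slope_C - 1| and flags near-zero controls", {
  expect_equal(ptgr_ratio(1, 1)$ratio, 0)
  expect_equal(ptgr_ratio(2, 1)$ratio, 1)
  expect_equal(ptgr_ratio(-1, 1)$ratio, 2)
  und <- ptgr_ratio(1.5, 1e-9)
  expect_true(is.na(und$ratio))
  expect_true(und$ratio_undefined)
})

test_that("individual_ptgr is the residual from the control line", {
  expect_equal(individual_ptgr(0, 2.5, 0.9), 2.5)
  expect_equal(individual_ptgr(1.0, 0.8, 0.8), 0)
  expect_equal(individual_ptgr(1.0, 2.0, 0.8), 1.2)
})

test_that("call_dprgs applies BH within contrast and matches the stepwise oracle", {
  p <- c(0.001, 0.01, 0.02, 0.8)
  rec <- tibble::tibble(gene_id = letters[1:4], p = p,
                        delta_ptgr = c(1, -1, 1, -1))
  out <- call_dprgs(rec)
  expect_equal(out$fdr, bh_oracle(p))
  expect_equal(out$fdr, p.adjust(p, "BH"))
  expect_equal(out$direction, c("up", "down", "up", "down"))
  # all p = 1: zero DPRGs
  none <- call_dprgs(dplyr::mutate(rec, p = 1))
  expect_equal(sum(none$significant), 0L)
  # single test: fdr equals p
  one <- call_dprgs(tibble::tibble(gene_id = "a", p = 0.04, delta_ptgr = 1))
  expect_equal(one$fdr, 0.04)
  expect_true(one$significant)
  # fdr never below p
  expect_true(all(out$fdr >= out$p))
})

test_that("estimate_ptgr: relabeling disease and control negates delta and t", {
  sim <- small_sim(seed = 6)
  prep <- prepare_counts(sim$exon, sim$intron, sim$samples, sim$truth$genes)
  fit_fwd <- estimate_ptgr(prep$exon, prep$intron, sim$samples,
                           control_label = "control")
  fit_rev <- estimate_ptgr(prep$exon, prep$intron, sim$samples,
                           control_label = "disease")
  fwd <- dplyr::arrange(tidy(fit_fwd), gene_id)
  rev <- dplyr::arrange(tidy(fit_rev), gene_id)
  shared <- intersect(fwd$gene_id, rev$gene_id)
  fwd <- fwd[match(shared, fwd$gene_id), ]
  rev <- rev[match(shared, rev$gene_id), ]
  expect_equal(fwd$delta_ptgr, -rev$delta_ptgr, tolerance = 1e-10)
  expect_equal(fwd$t, -rev$t, tolerance = 1e-10)
  expect_equal(fwd$p, rev$p, tolerance = 1e-10)
  expect_equal(fwd$fdr, rev$fdr, tolerance = 1e-10)
})

test_that("estimate_ptgr is invariant to per-gene constant shifts (affine invariance)", {
  sim <- small_sim(seed = 7)
  prep <- prepare_counts(sim$exon, sim$intron, sim$samples, sim$truth$genes)
  fit_a <- estimate_ptgr(prep$exon, prep$intron, sim$samples)
  shifted <- prep$exon
  shifted[, -1] <- shifted[, -1] + 3.7
  fit_b <- estimate_ptgr(shifted, prep$intron, sim$samples)
  expect_equal(tidy(fit_a)$delta_ptgr, tidy(fit_b)$delta_ptgr, tolerance = 1e-9)
  expect_equal(tidy(fit_a)$p, tidy(fit_b)$p, tolerance = 1e-9)
})

test_that("tidy/glance/individual outputs are coherent", {
  sim <- small_sim(seed = 8)
  prep <- prepare_counts(sim$exon, sim$intron, sim$samples, sim$truth$genes)
  fit <- estimate_ptgr(prep$exon, prep$intron, sim$samples)
  rec <- tidy(fit)
  gl <- glance(fit)
  expect_equal(gl$n_tested, nrow(rec))
  expect_equal(gl$n_dprg, sum(rec$significant))
  expect_true(all(rec$direction[rec$delta_ptgr > 0] == "up"))
  # per-individual scores reproduce the formula against stored deltas
  ind <- fit$individual
  g <- ind$gene_id[1]; s <- ind$sample_id[1]
  slope_c <- rec$slope_ctrl[rec$gene_id == g][1]
  expect_equal(ind$value[1],
               fit$deltas$exon[g, s] - fit$deltas$intron[g, s] * slope_c)
  # skipped genes are reported, not silently dropped
  expect_true(all(c("gene_id", "group", "reason") %in% names(fit$skipped)))
})

test_that("two-condition mode subtracts delta-intron from delta-exon directly", {
  sim <- small_sim(seed = 9, n_ctrl = 6, n_disease = 6)
  prep <- prepare_counts(sim$exon, sim$intron, sim$samples, sim$truth$genes)
  tc <- ptgr_two_condition(prep$exon, prep$intron, sim$samples)
  expect_equal(tc$genes$delta_ptgr, tc$genes$delta_exon - tc$genes$delta_intron)
  # one individual score per gene per condition sample (slope fixed at 1)
  expect_equal(nrow(tc$individual), nrow(tc$genes) * 6)
})
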