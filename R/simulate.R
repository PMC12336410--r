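# synthetic_data: exon/intron negative-binomial count matrices with known
# per-gene, per-group slopes on the log scale, sample tables with nuisance
# covariates, UTR sequences with planted motifs, and ground-truth
# evaluation. Counts are simulated at the count level so the TMM/log-CPM/
# TPM stages are genuinely exercised, not just the regression.

#' Simulation configuration
#'
#' Defines the generative model: per gene g and sample i, the latent
#' intronic log2 expression is `x_gi = baseline_g + N(0, intron_spread)`,
#' the latent exonic log2 expression is
#' `y_gi = a_g + slope_{g, group(i)} * x_gi + N(0, residual_sd)` with
#' `a_g` chosen so exonic and intronic means coincide; optional covariate
#' shifts are added to both latents; counts are drawn negative-binomially
#' with mean `2^latent * lib_size_i / 1e6` and the given dispersion
#' (`dispersion = 0` gives Poisson counts). A `perturbed_fraction` of genes
#' gets its disease slope shifted by `delta`.
#'
#' @param seed Mandatory RNG seed (integer below 2^31).
#' @param n_genes,n_ctrl,n_disease Problem size.
#' @param baseline_mean,baseline_sd Distribution of per-gene baseline
#'   intronic log2 expression.
#' @param intron_spread Per-sample sd of the latent intronic log2 signal.
#' @param slope_ctrl_mean,slope_ctrl_sd Distribution of true control slopes.
#' @param perturbed_fraction,delta Fraction of genes with a disease slope
#'   shift, and the shift.
#' @param residual_sd Exonic residual sd on the log2 scale.
#' @param dispersion Negative-binomial dispersion (1/size); 0 for Poisson.
#' @param lib_size_range Uniform range of per-sample library sizes.
#' @param gene_length_range Uniform range of composite exon lengths (bases).
#' @param covariates Named list of nuisance covariate specs, each
#'   `list(type = "numeric", effect = <coef>)` or
#'   `list(type = "categorical", levels = k, effect = <length-k shifts>)`.
#' @param control_label,disease_label Diagnosis labels.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed, n_genes = 2000L, n_ctrl = 100L, n_disease = 100L,
                       baseline_mean = 6.5, baseline_sd = 1.2,
                       intron_spread = 1.0,
                       slope_ctrl_mean = 1.0, slope_ctrl_sd = 0.1,
                       perturbed_fraction = 0.1, delta = 0.5,
                       residual_sd = 0.3, dispersion = 0.05,
                       lib_size_range = c(5e6, 2e7),
                       gene_length_range = c(500L, 5000L),
                       covariates = list(),
                       control_label = "control", disease_label = "disease") {
  if (missing(seed)) abort("`seed` is mandatory in sim_config()")
  stopifnot(n_genes > 0, n_ctrl > 1, n_disease > 1,
            baseline_sd >= 0, intron_spread > 0, slope_ctrl_sd >= 0,
            residual_sd >= 0, dispersion >= 0,
            length(lib_size_range) == 2L, all(lib_size_range > 0))
  if (perturbed_fraction < 0 || perturbed_fraction > 1) {
    abort("perturbed_fraction must lie in [0, 1]")
  }
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 n_ctrl = as.integer(n_ctrl), n_disease = as.integer(n_disease),
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 intron_spread = intron_spread,
                 slope_ctrl_mean = slope_ctrl_mean, slope_ctrl_sd = slope_ctrl_sd,
                 perturbed_fraction = perturbed_fraction, delta = delta,
                 residual_sd = residual_sd, dispersion = dispersion,
                 lib_size_range = lib_size_range,
                 gene_length_range = gene_length_range,
                 covariates = covariates,
                 control_label = control_label, disease_label = disease_label),
            class = "sim_config")
}

draw_counts <- function(mu, dispersion) {
  if (dispersion == 0) {
    stats::rpois(length(mu), lambda = mu)
  } else {
    rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  }
}

#' Simulate an exon/intron count matrix pair with known truth
#'
#' @param cfg A [sim_config()].
#' @return List with `exon`, `intron` (wide count tibbles), `samples`
#'   (sample table incl. any covariate columns) and `truth` (list:
#'   per-gene tibble with true slopes, perturbation flags and lengths;
#'   per-sample library sizes; the config). Bit-identical for a given seed.
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_fixed_seed(cfg$seed, {
    genes <- sprintf("g%04d", seq_len(cfg$n_genes))
    baseline <- rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)
    slope_ctrl <- rnorm(cfg$n_genes, cfg$slope_ctrl_mean, cfg$slope_ctrl_sd)
    n_pert <- round(cfg$perturbed_fraction * cfg$n_genes)
    perturbed <- rep(FALSE, cfg$n_genes)
    if (n_pert > 0) perturbed[sample.int(cfg$n_genes, n_pert)] <- TRUE
    slope_dis <- slope_ctrl + cfg$delta * perturbed
    intercept <- baseline * (1 - slope_ctrl)
    gene_len <- round(runif(cfg$n_genes, cfg$gene_length_range[1],
                            cfg$gene_length_range[2]))

    n_samp <- cfg$n_ctrl + cfg$n_disease
    sample_id <- c(sprintf("c%03d", seq_len(cfg$n_ctrl)),
                   sprintf("d%03d", seq_len(cfg$n_disease)))
    diagnosis <- rep(c(cfg$control_label, cfg$disease_label),
                     c(cfg$n_ctrl, cfg$n_disease))
    lib <- round(runif(n_samp, cfg$lib_size_range[1], cfg$lib_size_range[2]))

    # per-sample covariate shifts (added to both latents)
    shift <- numeric(n_samp)
    cov_cols <- list()
    for (nm in names(cfg$covariates)) {
      spec <- cfg$covariates[[nm]]
      if (identical(spec$type, "categorical")) {
        lev <- sample.int(spec$levels, n_samp, replace = TRUE)
        shift <- shift + spec$effect[lev]
        cov_cols[[nm]] <- paste0(nm, lev)
      } else {
        val <- rnorm(n_samp)
        shift <- shift + spec$effect * val
        cov_cols[[nm]] <- val
      }
    }

    x_lat <- baseline +
      matrix(rnorm(cfg$n_genes * n_samp, 0, cfg$intron_spread), cfg$n_genes)
    slope_mat <- cbind(matrix(slope_ctrl, cfg$n_genes, cfg$n_ctrl),
                       matrix(slope_dis, cfg$n_genes, cfg$n_disease))
    y_lat <- intercept + slope_mat * x_lat +
      matrix(rnorm(cfg$n_genes * n_samp, 0, cfg$residual_sd), cfg$n_genes)
    x_lat <- sweep(x_lat, 2, shift, "+")
    y_lat <- sweep(y_lat, 2, shift, "+")

    mu_x <- sweep(2^x_lat, 2, lib / 1e6, "*")
    mu_y <- sweep(2^y_lat, 2, lib / 1e6, "*")
    intron <- matrix(draw_counts(mu_x, cfg$dispersion), cfg$n_genes,
                     dimnames = list(genes, sample_id))
    exon <- matrix(draw_counts(mu_y, cfg$dispersion), cfg$n_genes,
                   dimnames = list(genes, sample_id))

    samples <- tibble(sample_id = sample_id, subject_id = sample_id,
                      diagnosis = diagnosis)
    for (nm in names(cov_cols)) samples[[nm]] <- cov_cols[[nm]]

    truth <- list(
      genes = tibble(gene_id = genes, baseline = baseline,
                     slope_ctrl = slope_ctrl, slope_dis = slope_dis,
                     perturbed = perturbed, exon_length = gene_len),
      lib_sizes = tibble(sample_id = sample_id, lib_size = lib),
      config = cfg
    )
    list(exon = matrix_to_wide(exon), intron = matrix_to_wide(intron),
         samples = samples, truth = truth)
  })
}

#' Random sharp PFMs for simulations
#'
#' Per-position probabilities are drawn from a sparse Dirichlet
#' (concentration 0.3), giving informative motifs with a clear consensus.
#'
#' @param n Number of motifs.
#' @param length_range Motif width range (inclusive).
#' @param seed RNG seed.
#' @return A `pfm_set` with motif ids `m01`, `m02`, ...
#' @export
random_pfms <- function(n, length_range = c(6L, 8L), seed = 1L) {
  with_fixed_seed(seed, {
    mats <- lapply(seq_len(n), function(i) {
      w <- sample(seq(length_range[1], length_range[2]), 1)
      m <- matrix(stats::rgamma(w * 4, shape = 0.3), w, 4)
      m / rowSums(m)
    })
    names(mats) <- sprintf("m%02d", seq_len(n))
    pfm_set(mats)
  })
}

#' Simulate 3'UTR sequences with planted motif consensi
#'
#' Background sequences are i.i.d. uniform over A/C/G/T; each gene in the
#' planted map gets the consensus of its motif inserted (overwritten) at a
#' random position, recorded in the truth map.
#'
#' @param gene_ids Genes to simulate UTRs for.
#' @param planted Named character vector: `gene_id -> motif_id` for genes
#'   that receive an insertion (may be empty).
#' @param pfms A `pfm_set` covering every planted motif id.
#' @param utr_length UTR length in bases.
#' @param seed RNG seed.
#' @return List with `utrs` (tibble `gene_id`, `seq`, `length`, `eligible`)
#'   and `truth` (tibble `gene_id`, `motif_id`, `position`, 0-based).
#' @export
simulate_utrs <- function(gene_ids, planted = character(), pfms = NULL,
                          utr_length = 200L, seed = 1L) {
  if (length(planted)) {
    if (is.null(pfms)) abort("`pfms` required when motifs are planted")
    missing_m <- setdiff(unique(planted), pfms$motif_id)
    if (length(missing_m)) {
      abort(sprintf("planted motif(s) not in pfm set: %s",
                    paste(missing_m, collapse = ", ")))
    }
  }
  with_fixed_seed(seed, {
    seqs <- vapply(gene_ids, function(g) {
      paste(sample(PFM_BASES, utr_length, replace = TRUE), collapse = "")
    }, character(1))
    truth <- list()
    for (g in names(planted)) {
      cons <- pfm_consensus(pfms$pfm[[match(planted[[g]], pfms$motif_id)]])
      if (nchar(cons) > utr_length) {
        abort(sprintf("motif %s (width %d) longer than UTR length %d",
                      planted[[g]], nchar(cons), utr_length))
      }
      pos <- sample.int(utr_length - nchar(cons) + 1L, 1)
      s <- seqs[[g]]
      substr(s, pos, pos + nchar(cons) - 1L) <- cons
      seqs[[g]] <- s
      truth[[g]] <- tibble(gene_id = g, motif_id = planted[[g]],
                           position = pos - 1L)
    }
    list(utrs = tibble(gene_id = gene_ids, seq = unname(seqs),
                       length = utr_length, eligible = TRUE),
         truth = bind_rows(truth))
  })
}

#' Evaluate estimates against simulation truth
#'
#' Dispatches on the estimate table: a `motif_id` column triggers regulator
#' evaluation (recovery and coefficient-sign accuracy of planted motifs,
#' false selections among nulls at `alpha`); otherwise delta-PTGR records
#' are evaluated (control-slope bias and RMSE, DPRG sensitivity,
#' specificity and observed false-discovery proportion at the recorded
#' significance calls, and direction accuracy among true positives). An
#' empty call set has sensitivity 0 and FDP 0 by convention.
#'
#' @param estimates A `ptgr_fit` record tibble (with `significant`) or an
#'   `rbp_fit` results tibble.
#' @param truth The `truth` element of [simulate_counts()] output, or for
#'   regulators a tibble with `motif_id` and `effect` (signed planted
#'   effects; motifs absent from it are nulls).
#' @param alpha Raw-p selection cutoff for regulator evaluation.
#' @return One-row metrics tibble.
#' @export
truth_eval <- function(estimates, truth, alpha = 0.05) {
  estimates <- if (inherits(estimates, "rbp_fit")) estimates$results else as_tibble(estimates)
  if ("motif_id" %in% names(estimates)) {
    truth <- as_tibble(truth)
    planted <- estimates$motif_id %in% truth$motif_id
    selected <- !is.na(estimates$p) & estimates$p < alpha
    eff <- truth$effect[match(estimates$motif_id, truth$motif_id)]
    sign_ok <- selected & planted & sign(estimates$beta) == sign(eff)
    return(tibble(
      n_planted = sum(planted), n_selected = sum(selected),
      planted_recovered = sum(selected & planted),
      sign_correct = sum(sign_ok),
      false_selections = sum(selected & !planted)
    ))
  }
  truth_genes <- truth$genes
  missing <- setdiff(estimates$gene_id, truth_genes$gene_id)
  if (length(missing)) {
    abort(sprintf("estimate gene id(s) absent from truth: %s",
                  paste(utils::head(missing, 5), collapse = ", ")))
  }
  tg <- truth_genes[match(estimates$gene_id, truth_genes$gene_id), ]
  called <- if ("significant" %in% names(estimates)) estimates$significant else rep(FALSE, nrow(estimates))
  tp <- sum(called & tg$perturbed)
  slope_err <- estimates$slope_ctrl - tg$slope_ctrl
  true_ratio <- abs(tg$slope_dis / tg$slope_ctrl - 1)
  dir_true <- ifelse(tg$slope_dis - tg$slope_ctrl > 0, "up", "down")
  dir_ok <- called & tg$perturbed & estimates$direction == dir_true
  tibble(
    n_genes = nrow(estimates),
    n_perturbed = sum(tg$perturbed),
    n_called = sum(called),
    sensitivity = if (sum(tg$perturbed) == 0) NA_real_ else tp / sum(tg$perturbed),
    specificity = if (sum(!tg$perturbed) == 0) NA_real_ else
      sum(!called & !tg$perturbed) / sum(!tg$perturbed),
    fdp = if (sum(called) == 0) 0 else sum(called & !tg$perturbed) / sum(called),
    direction_accuracy = if (tp == 0) NA_real_ else sum(dir_ok) / tp,
    slope_bias = mean(slope_err),
    slope_rmse = sqrt(mean(slope_err^2)),
    mean_ratio_est = mean(estimates$ratio, na.rm = TRUE),
    mean_ratio_true = mean(true_ratio)
  )
}
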