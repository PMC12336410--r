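# Huber M-estimated straight line via IRLS, with the robust asymptotic
# standard error. Kept free of lm()/rlm() so the per-gene loop over
# thousands of genes stays cheap; MASS::rlm is used only as an independent
# cross-check in the test suite.

#' Robust straight-line fit (Huber/bisquare IRLS)
#'
#' Fits `y ~ intercept + slope * x` by iteratively reweighted least squares
#' with the Huber psi (tuning constant 1.345) or Tukey bisquare (4.685).
#' The residual scale is re-estimated each iteration as the MAD; iteration
#' stops when coefficients move by less than `tol` (relative) or after
#' `max_iter` rounds. The slope standard error comes from the standard
#' M-estimation asymptotic covariance
#' `K^2 * [sum(psi^2 s^2)/(n-p)] / mean(psi')^2 * (X'X)^{-1}` with Huber's
#' small-sample correction `K = 1 + p/n * var(psi')/mean(psi')^2`.
#'
#' @param x,y Numeric vectors of equal length (finite pairs are used).
#' @param psi `"huber"` or `"bisquare"`.
#' @param k Tuning constant; defaults to 1.345 (Huber) or 4.685 (bisquare).
#' @param max_iter,tol IRLS iteration cap and relative convergence tolerance.
#' @return One-row tibble: `slope`, `se`, `intercept`, `sigma`, `n`,
#'   `converged`, `iterations`.
#' @export
huber_line <- function(x, y, psi = c("huber", "bisquare"), k = NULL,
                       max_iter = 50L, tol = 1e-8) {
  psi <- match.arg(psi)
  k <- k %||% if (psi == "huber") 1.345 else 4.685
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) abort("need at least 3 finite (x, y) pairs")
  sxx0 <- sum((x - mean(x))^2)
  if (sxx0 <= 0) abort("x has zero spread; slope is unidentifiable")

  # OLS start
  b <- sxx_cov(x, y) / sxx0
  a <- mean(y) - b * mean(x)

  w <- rep(1, n)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    r <- y - a - b * x
    s <- stats::median(abs(r)) / 0.6744898
    s <- max(s, 1e-8)
    u <- r / s
    w <- psi_weight(u, k, psi)
    sw <- sum(w)
    xw <- sum(w * x) / sw
    yw <- sum(w * y) / sw
    denom <- sum(w * (x - xw)^2)
    if (denom <= 0) break
    b_new <- sum(w * (x - xw) * (y - yw)) / denom
    a_new <- yw - b_new * xw
    delta <- max(abs(b_new - b), abs(a_new - a))
    scale_ref <- max(1, abs(a), abs(b))
    a <- a_new; b <- b_new
    if (delta < tol * scale_ref) {
      converged <- TRUE
      break
    }
  }

  r <- y - a - b * x
  s <- max(stats::median(abs(r)) / 0.6744898, 1e-8)
  u <- r / s
  psi_u <- psi_value(u, k, psi)
  psi_p <- psi_prime(u, k, psi)
  p <- 2L
  m1 <- mean(psi_p)
  se <- NA_real_
  if (m1 > 0) {
    kcorr <- 1 + (p / n) * stats::var(psi_p) / m1^2
    s2 <- kcorr^2 * sum((psi_u * s)^2) / (n - p) / m1^2
    se <- sqrt(s2 / sxx0)
  }
  tibble(slope = b, se = se, intercept = a, sigma = s, n = n,
         converged = converged, iterations = iter)
}

sxx_cov <- function(x, y) sum((x - mean(x)) * (y - mean(y)))

psi_weight <- function(u, k, psi) {
  if (psi == "huber") {
    pmin(1, k / pmax(abs(u), 1e-12))
  } else {
    w <- (1 - (u / k)^2)^2
    w[abs(u) > k] <- 0
    w
  }
}

psi_value <- function(u, k, psi) {
  if (psi == "huber") {
    pmax(-k, pmin(k, u))
  } else {
    v <- u * (1 - (u / k)^2)^2
    v[abs(u) > k] <- 0
    v
  }
}

psi_prime <- function(u, k, psi) {
  if (psi == "huber") {
    as.numeric(abs(u) <= k)
  } else {
    t2 <- (u / k)^2
    d <- (1 - t2) * (1 - 5 * t2)
    d[abs(u) > k] <- 0
    d
  }
}

#' Per-group robust slope of delta-exon on delta-intron
#'
#' Wraps [huber_line()] with the gate-keeping the per-gene pipeline needs: a
#' minimum number of paired finite observations and a non-degenerate
#' predictor (positive MAD). Gated-out genes are returned as skip records
#' with a reason, never silently dropped.
#'
#' @param dx Delta-intron values for one gene within one group.
#' @param dy Delta-exon values, aligned with `dx`.
#' @param min_fit_n Minimum paired observations (default 10).
#' @inheritParams huber_line
#' @return One-row tibble: `slope`, `se`, `intercept`, `sigma`, `n`,
#'   `converged`, `skipped`, `reason`.
#' @export
fit_group_slope <- function(dx, dy, min_fit_n = 10L, psi = "huber", k = NULL,
                            max_iter = 50L, tol = 1e-8) {
  ok <- is.finite(dx) & is.finite(dy)
  n_ok <- sum(ok)
  skip <- function(reason) {
    tibble(slope = NA_real_, se = NA_real_, intercept = NA_real_,
           sigma = NA_real_, n = n_ok, converged = NA,
           skipped = TRUE, reason = reason)
  }
  if (n_ok < min_fit_n) return(skip(sprintf("n = %d below min_fit_n = %d", n_ok, min_fit_n)))
  if (stats::mad(dx[ok]) == 0) return(skip("degenerate predictor (MAD = 0)"))
  fit <- huber_line(dx[ok], dy[ok], psi = psi, k = k,
                    max_iter = max_iter, tol = tol)
  fit |>
    select(-"iterations") |>
    mutate(skipped = FALSE, reason = NA_character_)
}
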