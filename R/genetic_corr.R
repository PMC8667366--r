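#' Compute LD scores from a reference panel
#'
#' The LD score of SNP j is the sum of squared correlations with SNPs within
#' `window_bp` on the same chromosome (under block LD only same-block
#' neighbors contribute), using the bias-adjusted estimator
#' `r2_adj = r^2 - (1 - r^2) / (n_ref - 2)` that removes the upward finite-
#' sample bias of squared sample correlations.
#'
#' @param ld an `ld_reference`.
#' @param window_bp window half-width in base pairs (default 10 Mb).
#' @param n_ref reference-panel sample size for the bias adjustment; `Inf`
#'   disables it. Defaults to the panel's own `n_ref`.
#' @return a list with `ell` (per-SNP LD scores, ordered as `ld$snp_index`)
#'   and `M` (number of contributing SNPs).
#' @export
compute_ld_scores <- function(ld, window_bp = 10e6, n_ref = ld$n_ref) {
  stopifnot(window_bp > 0)
  idx <- ld$snp_index
  ell <- numeric(nrow(idx))
  adj <- function(r2) if (is.finite(n_ref)) r2 - (1 - r2) / (n_ref - 2) else r2
  for (b in seq_along(ld$blocks)) {
    jj <- which(idx$block == b)
    R2 <- adj(ld$blocks[[b]]^2)
    inwin <- abs(outer(idx$pos[jj], idx$pos[jj], "-")) <= window_bp
    ell[jj] <- rowSums(R2 * inwin)
  }
  list(ell = ell, M = nrow(idx))
}

# weighted OLS of y on x with intercept and delete-one-block jackknife;
# returns coef (intercept, slope) and per-deleted-block coefficient matrix
.wls_jackknife <- function(x, y, w, n_blocks) {
  n <- length(y)
  n_blocks <- min(n_blocks, n)
  blk <- ceiling(seq_len(n) / (n / n_blocks))
  # per-block sufficient statistics of the weighted normal equations
  a11 <- rowsum(w, blk); a12 <- rowsum(w * x, blk); a22 <- rowsum(w * x * x, blk)
  b1 <- rowsum(w * y, blk); b2 <- rowsum(w * x * y, blk)
  solve2 <- function(s11, s12, s22, t1, t2) {
    det <- s11 * s22 - s12^2
    c((s22 * t1 - s12 * t2) / det, (s11 * t2 - s12 * t1) / det)
  }
  tot <- c(sum(a11), sum(a12), sum(a22), sum(b1), sum(b2))
  coef <- solve2(tot[1], tot[2], tot[3], tot[4], tot[5])
  B <- length(a11)
  jack <- matrix(NA_real_, B, 2)
  for (b in seq_len(B))
    jack[b, ] <- solve2(tot[1] - a11[b], tot[2] - a12[b], tot[3] - a22[b],
                        tot[4] - b1[b], tot[5] - b2[b])
  se <- sqrt((B - 1) / B * colSums(sweep(jack, 2, colMeans(jack))^2))
  list(coef = coef, se = se, jack = jack, n_blocks = B)
}

#' Genomic inflation factor
#'
#' `lambda = median(z^2) / qchisq(0.5, 1)`, the ratio of the observed median
#' association chi-square to its null median.
#'
#' @param z_vec association Z-statistics.
#' @return the inflation factor.
#' @export
genomic_lambda <- function(z_vec) {
  stats::median(z_vec^2) / stats::qchisq(0.5, df = 1)
}

#' Univariate LD score regression: heritability and intercept
#'
#' Regresses per-SNP chi-squares on LD scores,
#' `E[chi2_j] = intercept + (N h2 / M) ell_j`, with the standard
#' heteroskedasticity/overcounting weights
#' `w_j = 1 / (max(ell_j, 1) * (1 + N h2 ell_j / M)^2)` iterated twice from
#' an OLS start; standard errors by delete-a-block jackknife over contiguous
#' SNP blocks.
#'
#' @param ss a `summary_stats` table (at least 200 SNPs), aligned to the LD
#'   scores (same SNPs, same order).
#' @param scores output of [compute_ld_scores()].
#' @param n_blocks jackknife blocks (reduced with a warning when there are
#'   fewer SNPs than blocks).
#' @return a list of class `ldsc_fit` with `h2, intercept, se_h2,
#'   se_intercept, lambda_gc, n_blocks_jackknife` and the fitted weights.
#' @export
ldsc_h2 <- function(ss, scores, n_blocks = 200L) {
  stopifnot(nrow(ss) >= 200, nrow(ss) == length(scores$ell))
  if (nrow(ss) < n_blocks) {
    warning("fewer SNPs than jackknife blocks; reducing blocks")
    n_blocks <- nrow(ss)
  }
  ell <- scores$ell; M <- scores$M
  chi2 <- ss$z^2
  N <- stats::median(ss$n)
  ellw <- pmax(ell, 1)
  w <- rep(1, length(ell))
  fit <- NULL
  for (i in 1:3) {  # OLS start + two weighted refits
    fit <- .wls_jackknife(ell, chi2, w, n_blocks)
    h2_cur <- max(0, fit$coef[2] * M / N)
    w <- 1 / (ellw * (1 + N * h2_cur * ellw / M)^2)
  }
  structure(list(h2 = fit$coef[2] * M / N, intercept = fit$coef[1],
                 se_h2 = fit$se[2] * M / N, se_intercept = fit$se[1],
                 lambda_gc = genomic_lambda(ss$z),
                 n_blocks_jackknife = fit$n_blocks,
                 weights = w, slope = fit$coef[2], jack = fit$jack,
                 M = M, N = N),
            class = "ldsc_fit")
}

#' Cross-trait LD score regression: genetic covariance and correlation
#'
#' Regresses the per-SNP product of Z-statistics on LD scores,
#' `E[z1_j z2_j] = gcov_intercept + (sqrt(N1 N2) rho_g / M) ell_j`. The
#' intercept estimates the sample-overlap term `rho * Ns / sqrt(N1 N2)`; the
#' genetic correlation is `rg = rho_g / sqrt(h2_1 h2_2)` with heritabilities
#' from [ldsc_h2()]. The jackknife recomputes all three regressions per
#' deleted block, so the `rg` standard error propagates the heritability
#' uncertainty.
#'
#' @param ss1,ss2 `summary_stats` for the two traits, aligned to the LD
#'   scores.
#' @param scores output of [compute_ld_scores()].
#' @param n_blocks jackknife blocks.
#' @return a list of class `ldsc_rg_fit` with `rg, se_rg, gencov,
#'   gcov_intercept, se_gcov_intercept, h2_1, h2_2`, and the per-trait fits.
#' @export
ldsc_rg <- function(ss1, ss2, scores, n_blocks = 200L) {
  stopifnot(nrow(ss1) == nrow(ss2), nrow(ss1) == length(scores$ell))
  f1 <- ldsc_h2(ss1, scores, n_blocks)
  f2 <- ldsc_h2(ss2, scores, n_blocks)
  ell <- scores$ell; M <- scores$M
  ellw <- pmax(ell, 1)
  N1 <- f1$N; N2 <- f2$N
  y <- ss1$z * ss2$z

  w <- rep(1, length(ell))
  fit <- NULL
  for (i in 1:3) {
    fit <- .wls_jackknife(ell, y, w, n_blocks)
    rhog <- fit$coef[2] * M / sqrt(N1 * N2)
    icpt <- fit$coef[1]
    v1 <- 1 + N1 * max(0, f1$h2) * ellw / M
    v2 <- 1 + N2 * max(0, f2$h2) * ellw / M
    cterm <- sqrt(N1 * N2) * rhog * ellw / M + icpt
    w <- 1 / (ellw * (v1 * v2 + cterm^2))
  }
  gencov <- fit$coef[2] * M / sqrt(N1 * N2)
  h2_ok <- f1$h2 > 0 && f2$h2 > 0
  rg <- if (h2_ok) gencov / sqrt(f1$h2 * f2$h2) else NA_real_

  # jackknife on rg combining the three per-block coefficient paths
  B <- min(nrow(fit$jack), nrow(f1$jack), nrow(f2$jack))
  se_rg <- NA_real_
  if (h2_ok && B > 1) {
    rg_b <- vapply(seq_len(B), function(b) {
      g <- fit$jack[b, 2] * M / sqrt(N1 * N2)
      h1 <- f1$jack[b, 2] * M / N1
      h2 <- f2$jack[b, 2] * M / N2
      if (h1 > 0 && h2 > 0) g / sqrt(h1 * h2) else NA_real_
    }, numeric(1))
    rg_b <- rg_b[is.finite(rg_b)]
    if (length(rg_b) > 1)
      se_rg <- sqrt((length(rg_b) - 1) / length(rg_b) *
                      sum((rg_b - mean(rg_b))^2))
  }
  flagged <- is.finite(rg) && abs(rg) > 1.25
  structure(list(rg = rg, se_rg = se_rg, gencov = gencov,
                 gcov_intercept = fit$coef[1], se_gcov_intercept = fit$se[1],
                 h2_1 = f1$h2, h2_2 = f2$h2, fit1 = f1, fit2 = f2,
                 n_blocks_jackknife = fit$n_blocks, out_of_range = flagged),
            class = "ldsc_rg_fit")
}

#' Hierarchical clustering of a trait genetic-correlation matrix
#'
#' Clusters traits with average-linkage agglomeration on the distance
#' `d = 1 - rg`; missing correlations are imputed as 0 with a warning. The
#' resulting partition is invariant to trait ordering.
#'
#' @param rg_matrix symmetric genetic-correlation matrix with unit diagonal
#'   and trait names on the dimnames.
#' @param k number of clusters to cut at (default 3).
#' @param method linkage method passed to [stats::hclust()].
#' @return a list with `hclust` (the tree) and `labels` (named cluster
#'   assignments at `k`).
#' @export
cluster_traits <- function(rg_matrix, k = 3L, method = "average") {
  stopifnot(nrow(rg_matrix) == ncol(rg_matrix))
  if (anyNA(rg_matrix)) {
    warning("missing rg entries imputed as 0")
    rg_matrix[is.na(rg_matrix)] <- 0
  }
  rg_matrix <- (rg_matrix + t(rg_matrix)) / 2
  diag(rg_matrix) <- 1
  d <- stats::as.dist(1 - rg_matrix)
  hc <- stats::hclust(d, method = method)
  k <- min(k, nrow(rg_matrix))
  list(hclust = hc, labels = stats::cutree(hc, k = k))
}
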