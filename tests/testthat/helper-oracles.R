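# Independent brute-force oracles. These deliberately re-derive each
# quantity from its definition, without calling the implementation paths
# they are used to check.

# step-up FDR from the definition: q_(i) = min over j >= i of c * p_(j) * n / j
bf_stepup <- function(p, harmonic = FALSE) {
  n <- length(p)
  cm <- if (harmonic) sum(1 / seq_len(n)) else 1
  ord <- order(p)
  q_sorted <- cm * p[ord] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# Monte-Carlo tail of sum(lambda_i * chisq_1)
mc_wsum_chisq_tail <- function(S, lambda, n_draws = 2e5) {
  draws <- numeric(n_draws)
  for (lam in lambda) draws <- draws + lam * stats::rchisq(n_draws, df = 1)
  mean(draws >= S)
}

# Monte-Carlo two-sided tail of the product of two standard normals,
# evaluated at several thresholds from one big sample (chunked)
mc_product_tail <- function(t_vals, n_draws = 1e7, chunk = 1e6) {
  counts <- numeric(length(t_vals))
  done <- 0
  while (done < n_draws) {
    k <- min(chunk, n_draws - done)
    w <- abs(stats::rnorm(k) * stats::rnorm(k))
    counts <- counts + vapply(abs(t_vals), function(t) sum(w >= t), numeric(1))
    done <- done + k
  }
  counts / n_draws
}

# hypergeometric upper tail from the counting definition
bf_hypergeom_tail <- function(N, K, n_draw, k_obs) {
  j <- k_obs:min(K, n_draw)
  sum(choose(K, j) * choose(N - K, n_draw - j)) / choose(N, n_draw)
}

# greedy clumping re-derived from its definition; r2_fun(id1, id2) supplies
# pairwise squared correlation
bf_clump <- function(cand, r2_fun, p_thresh, r2_thresh, dist_bp) {
  cand <- cand[cand$p < p_thresh, ]
  cand <- cand[order(cand$p, cand$pos, cand$snp_id), ]
  kept <- character(0)
  while (nrow(cand) > 0) {
    top <- cand[1, ]
    kept <- c(kept, top$snp_id)
    drop <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))[-1]) {
      near <- cand$chrom[i] == top$chrom &&
        abs(cand$pos[i] - top$pos) <= dist_bp
      if (near && r2_fun(top$snp_id, cand$snp_id[i]) > r2_thresh)
        drop[i] <- TRUE
    }
    cand <- cand[-1, ][!drop[-1], ]
  }
  kept
}
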