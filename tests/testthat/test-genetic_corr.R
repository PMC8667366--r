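test_that("LD scores follow their closed forms and a summation oracle", {
  # identity LD, no finite-sample adjustment: ell = 1 everywhere
  ld0 <- simulate_ld_reference(n_blocks = 4L, block_size = 10L, rho_ar1 = 0,
                               seed = 1L)
  s0 <- compute_ld_scores(ld0, n_ref = Inf)
  expect_equal(s0$ell, rep(1, 40))
  expect_equal(s0$M, 40L)

  # a block of k perfectly correlated SNPs: ell = k
  ld1 <- simulate_ld_reference(n_blocks = 1L, block_size = 5L, rho_ar1 = 0,
                               seed = 1L)
  ld1$blocks[[1]] <- matrix(1, 5, 5)
  expect_equal(compute_ld_scores(ld1, n_ref = Inf)$ell, rep(5, 5))

  # AR(1) block against direct double-loop summation with the bias term
  ld2 <- simulate_ld_reference(n_blocks = 2L, block_size = 8L, rho_ar1 = 0.7,
                               seed = 2L)
  s2 <- compute_ld_scores(ld2, n_ref = 503)
  idx <- ld2$snp_index
  oracle <- vapply(seq_len(nrow(idx)), function(j) {
    tot <- 0
    for (k in seq_len(nrow(idx))) {
      same_block <- idx$block[j] == idx$block[k]
      r2 <- if (same_block)
        ld2$blocks[[idx$block[j]]][sum(idx$block[seq_len(j)] == idx$block[j]),
                                   sum(idx$block[seq_len(k)] == idx$block[k])]^2
      else 0
      if (same_block && abs(idx$pos[j] - idx$pos[k]) <= 10e6)
        tot <- tot + (r2 - (1 - r2) / (503 - 2))
    }
    tot
  }, numeric(1))
  expect_equal(s2$ell, oracle, tolerance = 1e-12)

  # window restriction drops distant pairs
  s_narrow <- compute_ld_scores(ld2, window_bp = 5000, n_ref = Inf)
  expect_true(all(s_narrow$ell <= compute_ld_scores(ld2, n_ref = Inf)$ell + 1e-12))
})

test_that("genomic lambda is the median chi-square ratio", {
  med <- sqrt(stats::qchisq(0.5, 1))
  expect_equal(genomic_lambda(c(-med, med, med)), 1)
  set.seed(51)
  z <- rnorm(101)
  expect_equal(genomic_lambda(2 * z), 4 * genomic_lambda(z))
  z_null <- rnorm(2e5)
  expect_lt(abs(genomic_lambda(z_null) - 1), 0.02)
})

test_that("a constant chi-square vector yields slope zero", {
  ld <- simulate_ld_reference(n_blocks = 10L, block_size = 30L, seed = 3L)
  sc <- compute_ld_scores(ld)
  ss <- as_summary_stats(data.table::data.table(
    snp_id = ld$snp_index$snp_id, chrom = ld$snp_index$chrom,
    pos = ld$snp_index$pos, a1 = ld$snp_index$a1, a2 = ld$snp_index$a2,
    maf = ld$snp_index$maf, beta = 0.01, se = 0.01, p = 0.317, n = 1000))
  expect_true(all(ss$z == 1))
  fit <- ldsc_h2(ss, sc)
  expect_equal(fit$h2, 0, tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
})

test_that("LDSC is calibrated under the pure null", {
  arch <- architecture_spec(h2 = 0, overlap_rho = 0, rg = 0, n = 5e4)
  sc <- compute_ld_scores(.shared_ld)
  ints <- vapply(1:5, function(s) {
    sim <- simulate_summary_pair(.shared_ld, .shared_annot, arch, seed = 700 + s)
    f <- ldsc_h2(sim$ss1, sc)
    c(f$intercept, f$se_intercept, f$lambda_gc)
  }, numeric(3))
  # intercept within 3 jackknife SEs of 1 in each replicate
  expect_true(all(abs(ints[1, ] - 1) < 3 * ints[2, ]))
  expect_true(all(abs(ints[3, ] - 1) < 0.15))
})

test_that("cross-trait LDSC is exactly symmetric and near 1 on self-pairs", {
  arch <- architecture_spec(h2 = 0.3, rg = 0.5, overlap_rho = 0.1)
  sim <- simulate_summary_pair(.shared_ld, .shared_annot, arch, seed = 61L)
  sc <- compute_ld_scores(.shared_ld)
  f12 <- ldsc_rg(sim$ss1, sim$ss2, sc)
  f21 <- ldsc_rg(sim$ss2, sim$ss1, sc)
  expect_equal(f12$rg, f21$rg, tolerance = 1e-12)
  expect_equal(f12$gcov_intercept, f21$gcov_intercept, tolerance = 1e-12)

  fself <- ldsc_rg(sim$ss1, sim$ss1, sc)
  expect_lt(abs(fself$rg - 1), 0.05)
})

test_that("trait clustering recovers planted structure and ignores order", {
  traits <- paste0("T", 1:6)
  rg <- matrix(0, 6, 6, dimnames = list(traits, traits))
  rg[1:3, 1:3] <- 0.9; rg[4:6, 4:6] <- 0.9; diag(rg) <- 1
  cl <- cluster_traits(rg, k = 2)
  expect_length(unique(cl$labels[1:3]), 1L)
  expect_length(unique(cl$labels[4:6]), 1L)
  expect_false(cl$labels[1] == cl$labels[4])

  perm <- c(5, 2, 6, 1, 3, 4)
  cl_perm <- cluster_traits(rg[perm, perm], k = 2)
  same <- outer(cl$labels[traits[perm]], cl$labels[traits[perm]], "==")
  same_perm <- outer(cl_perm$labels, cl_perm$labels, "==")
  expect_equal(unname(same), unname(same_perm))

  expect_warning(cluster_traits(rbind(c(1, NA), c(NA, 1))), "imputed")

  # planted three-cluster structure with noise is recovered across seeds
  ok <- vapply(1:20, function(s) {
    set.seed(800 + s)
    truth <- rep(1:3, each = 4)
    m <- outer(truth, truth, function(a, b) ifelse(a == b, 0.7, 0.05)) +
      matrix(rnorm(144, 0, 0.04), 12)
    m <- (m + t(m)) / 2; diag(m) <- 1
    dimnames(m) <- list(paste0("X", 1:12), paste0("X", 1:12))
    lab <- cluster_traits(m, k = 3)$labels
    all(outer(lab, lab, "==") == outer(truth, truth, "=="))
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
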