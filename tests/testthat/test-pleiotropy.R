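test_that("null Z correlation is recovered and trimming guards against signal", {
  set.seed(31)
  z1 <- rnorm(5000); z2 <- rnorm(5000)
  expect_lt(abs(estimate_z_correlation(z1, z2)), 3 / sqrt(5000))
  expect_equal(estimate_z_correlation(z1, z1), 1)

  rho <- 0.3
  z2c <- rho * z1 + sqrt(1 - rho^2) * rnorm(5000)
  expect_lt(abs(estimate_z_correlation(z1, z2c) - rho), 3 / sqrt(5000))

  # planted signal genes are excluded by the trim, not absorbed into rho
  z1s <- c(z1, rep(9, 200)); z2s <- c(z2, rep(9, 200))
  expect_lt(abs(estimate_z_correlation(z1s, z2s)), 3 / sqrt(5000))
})

test_that("de-correlation removes the null correlation and is symmetric", {
  expect_equal(decorrelate_z(1.3, -0.4, 0), list(z1 = 1.3, z2 = -0.4))
  set.seed(32)
  z1 <- rnorm(20000)
  z2 <- 0.5 * z1 + sqrt(0.75) * rnorm(20000)
  d <- decorrelate_z(z1, z2, 0.5)
  expect_lt(abs(stats::cor(d$z1, d$z2)), 3 / sqrt(20000))
  expect_lt(abs(stats::var(d$z1) - 1), 0.05)
  # symmetry: swapping traits swaps outputs
  d_swap <- decorrelate_z(z2, z1, 0.5)
  expect_equal(d_swap$z1, d$z2)
  expect_error(decorrelate_z(1, 1, 0.995), "entangled")
})

test_that("product-normal tail obeys its exact identities", {
  expect_equal(product_normal_tail(0), 1)
  expect_equal(product_normal_tail(2, 2, 1), product_normal_tail(1, 1, 1))
  expect_equal(product_normal_tail(3, 1.5, 2),
               product_normal_tail(1, 1, 1))
  # monotone non-increasing in |t|
  tt <- seq(0, 12, by = 0.5)
  pp <- product_normal_tail(tt)
  expect_true(all(diff(pp) <= 0))
  expect_error(product_normal_tail(Inf), "finite")
})

test_that("product-normal tail matches a 1e7-draw Monte-Carlo oracle", {
  set.seed(33)
  t_vals <- c(0.1, 0.5, 1, 2, 3)
  n_mc <- 1e7
  emp <- mc_product_tail(t_vals, n_draws = n_mc)
  exact <- product_normal_tail(t_vals)
  mc_se <- sqrt(emp * (1 - emp) / n_mc)
  expect_true(all(abs(exact - emp) < 3 * mc_se))
})

test_that("sigma-squared estimation floors the marginal Z variance at 1", {
  set.seed(34)
  z <- rnorm(10000)
  s <- estimate_sigma_sq(z)
  expect_lt(abs(s - 1), 0.06)
  expect_equal(estimate_sigma_sq(1.5 * z), max(1, var(1.5 * z)))
  expect_lt(abs(estimate_sigma_sq(1.5 * z) - 2.25), 0.1)
  expect_equal(estimate_sigma_sq(rep(0, 100)), 1)
  expect_error(estimate_sigma_sq(rnorm(10)), "50")
})

test_that("the composite-null test reduces, symmetrizes, and stays valid", {
  expect_equal(placo_test(0, 1.7)$p_placo, 1)
  r12 <- placo_test(c(1.2, -2), c(0.7, 1.1), 2, 3)
  r21 <- placo_test(c(0.7, 1.1), c(1.2, -2), 3, 2)
  expect_equal(r12$p_placo, r21$p_placo)
  r <- placo_test(1.8, 2.2, 1, 1)
  expect_equal(r$p_placo, r$p00)
  expect_error(placo_test(1, 1, 0.5, 1), "sigma")

  # type-I error under H10 with estimated sigma (quick module-level check;
  # the full three-scenario calibration lives in the acceptance suite)
  set.seed(35)
  n <- 4000
  z1 <- rnorm(n, 0, 2)  # associated trait, inflated Z
  z2 <- rnorm(n)
  out <- placo_test(z1, z2, estimate_sigma_sq(z1), estimate_sigma_sq(z2))
  rate <- mean(out$p_placo < 0.05)
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / n))
})

test_that("BH and BY match the brute-force step-up definitions", {
  expect_equal(fdr_bh(0.03), 0.03)
  expect_equal(fdr_by(0.03), 0.03)
  expect_equal(fdr_bh(rep(0.2, 7)), rep(0.2, 7))
  set.seed(36)
  for (i in 1:20) {
    p <- runif(100)^sample(c(1, 2, 3), 1)
    expect_equal(fdr_bh(p), bf_stepup(p, harmonic = FALSE))
    expect_equal(fdr_by(p), bf_stepup(p, harmonic = TRUE))
  }
})

test_that("comparator methods equal their brute-force double-threshold forms", {
  expect_identical(direct_fdr_method(numeric(0), numeric(0)), character(0))
  set.seed(37)
  p1 <- stats::setNames(runif(200)^3, paste0("g", 1:200))
  p2 <- stats::setNames(runif(200)^3, paste0("g", 1:200))
  got <- direct_fdr_method(p1, p2, alpha = 0.1)
  want <- names(p1)[bf_stepup(p1) < 0.1 & bf_stepup(p2) < 0.1]
  expect_setequal(got, want)
  # significant in one trait only -> excluded
  p2_only <- p2; p2_only[] <- 0.9
  expect_length(direct_fdr_method(p1, p2_only, alpha = 0.1), 0)

  got_max <- max_p_method(p1, p2, alpha = 0.1)
  want_max <- names(p1)[bf_stepup(pmax(p1, p2)) < 0.1]
  expect_setequal(got_max, want_max)
  expect_equal(max_p_method(p1, p1, alpha = 0.1),
               names(p1)[bf_stepup(p1) < 0.1])
})

test_that("the overall-pleiotropy LRT is calibrated and powered", {
  gen <- function(pi1, pi2, pi11 = pi1 * pi2, n = 1500, seed) {
    set.seed(seed)
    pi <- c(1 - pi1 - pi2 + pi11, pi1 - pi11, pi2 - pi11, pi11)
    comp <- sample.int(4, n, replace = TRUE, prob = pi)
    p1 <- ifelse(comp %in% c(2, 4), rbeta(n, 0.15, 1), runif(n))
    p2 <- ifelse(comp %in% c(3, 4), rbeta(n, 0.15, 1), runif(n))
    list(p1 = p1, p2 = p2)
  }
  # independence null: rejection rate at 0.05 compatible with 0.05
  rej <- vapply(1:60, function(s) {
    d <- gen(0.15, 0.15, seed = 400 + s)
    overall_pleiotropy_lrt(d$p1, d$p2)$p_lrt < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.05 + 3 * sqrt(0.05 * 0.95 / 60))

  # strongly shared indicators: overwhelming rejection
  shared_p <- vapply(1:10, function(s) {
    d <- gen(0.2, 0.2, pi11 = 0.15, seed = 500 + s)
    overall_pleiotropy_lrt(d$p1, d$p2)$p_lrt
  }, numeric(1))
  expect_gte(mean(shared_p < 1e-4), 0.95)

  # all-uniform degenerate fit collapses
  set.seed(41)
  stats_null <- vapply(1:20, function(s) {
    set.seed(600 + s)
    overall_pleiotropy_lrt(runif(1000), runif(1000))$lrt_stat
  }, numeric(1))
  expect_gte(mean(stats_null < stats::qchisq(0.5, 1)), 0.5)
})

test_that("effect correlation and Cochran's Q follow their definitions", {
  b <- c(0.1, -0.2, 0.4, 0.05)
  expect_equal(effect_correlation(b, 2 * b), 1)
  expect_equal(effect_correlation(b, -b), -1)
  expect_true(is.na(effect_correlation(b[1:2], b[1:2])))
  set.seed(38)
  x <- rnorm(10); y <- rnorm(10)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(effect_correlation(x, y), r_hand)

  expect_equal(cochran_q(0.3, 0.1, 0.3, 0.2)$Q, 0)
  expect_equal(cochran_q(0.3, 0.1, 0.3, 0.2)$p_het, 1)
  q <- cochran_q(1, 1, 0, 1)
  expect_equal(q$Q, 0.5)
  expect_equal(q$p_het, stats::pchisq(0.5, 1, lower.tail = FALSE))
  expect_equal(cochran_q(1, 0.3, 0.2, 0.7), cochran_q(0.2, 0.7, 1, 0.3))
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  bg <- paste0("g", 1:20)
  set.seed(39)
  gene_set <- sample(bg, 5)
  query <- c(sample(gene_set, 4), sample(setdiff(bg, gene_set), 4))
  res <- hypergeometric_enrichment(query, gene_set, bg)
  expect_equal(res$overlap, 4L)
  # oracle 1: enumerate all 8-subsets of the background
  combos <- utils::combn(bg, 8)
  tail_enum <- mean(colSums(matrix(combos %in% gene_set, nrow = 8)) >= 4)
  expect_equal(res$p_enrich, tail_enum, tolerance = 1e-12)
  # oracle 2: counting formula on 20 random configurations
  for (i in 1:20) {
    N <- sample(20:60, 1); K <- sample(3:10, 1); nq <- sample(5:15, 1)
    bg2 <- paste0("h", 1:N)
    set2 <- sample(bg2, K); q2 <- sample(bg2, nq)
    k_obs <- length(intersect(q2, set2))
    expect_equal(hypergeometric_enrichment(q2, set2, bg2)$p_enrich,
                 bf_hypergeom_tail(N, K, nq, k_obs), tolerance = 1e-12)
  }
  # degenerate cases
  expect_equal(hypergeometric_enrichment(bg[1:3], bg[4:6], bg)$p_enrich, 1)
  expect_equal(hypergeometric_enrichment(bg, bg, bg)$overlap, 20L)
  expect_equal(hypergeometric_enrichment(bg, bg, bg)$p_enrich, 1)
})

test_that("shared-gene summaries recount a synthetic three-trait run", {
  empty <- shared_gene_summary(list())
  expect_equal(nrow(empty$pair_counts), 0L)
  expect_equal(nrow(empty$gene_trait_counts), 0L)

  mk <- function(ids, q, z1 = 1, z2 = 1)
    data.table::data.table(gene_id = ids, z1 = z1, z2 = z2, q_fdr = q)
  res <- list(
    "A|B" = mk(c("g1", "g2", "g3"), c(0.01, 0.2, 0.01)),
    "A|C" = mk(c("g1", "g4"), c(0.02, 0.8), z1 = -1),
    "B|C" = mk(c("g1", "g5"), c(0.9, 0.01), z2 = -2))
  s <- shared_gene_summary(res, alpha = 0.05)
  expect_equal(s$pair_counts$n_significant, c(2L, 1L, 1L))
  counts <- stats::setNames(s$gene_trait_counts$n_traits,
                            s$gene_trait_counts$gene_id)
  expect_equal(counts[["g1"]], 3L)  # A|B and A|C both involve g1
  expect_equal(counts[["g3"]], 2L)
  expect_equal(counts[["g5"]], 2L)
  # brute-force recount of trait links
  brute <- table(unlist(lapply(names(res), function(nm) {
    g <- res[[nm]]; tr <- strsplit(nm, "|", fixed = TRUE)[[1]]
    unlist(lapply(which(g$q_fdr < 0.05), function(i) paste0(g$gene_id[i], ":", tr)))
  })))
  brute_genes <- table(sub(":.*", "", names(brute)))
  expect_equal(sort(counts), sort(stats::setNames(as.integer(brute_genes),
                                                  names(brute_genes))))
})
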