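test_that("the MR design enumerates childhood and adulthood relationships", {
  child <- c("ASD", "ADHD")
  adult <- c("AD", "AN", "AUD", "OCD", "BIP", "SCZ", "PTSD", "TS", "CU", "MDD")
  d <- enumerate_mr_design(child, adult)
  expect_equal(nrow(d), 110L)
  expect_equal(sum(d$design == "childhood"), 20L)
  expect_equal(sum(d$design == "adulthood"), 90L)
  expect_equal(anyDuplicated(d[, c("exposure", "outcome")]), 0L)

  expect_equal(nrow(enumerate_mr_design(character(0), c("A", "B"))), 2L)
  expect_equal(nrow(enumerate_mr_design("A", character(0))), 0L)
  # deterministic order
  expect_identical(d, enumerate_mr_design(child, adult))
})

test_that("clumping keeps the smaller p of correlated neighbors and spares distant SNPs", {
  panel <- structure(list(
    blocks = list(matrix(c(1, sqrt(0.9), sqrt(0.9), 1), 2), matrix(1)),
    snp_index = data.table::data.table(
      snp_id = c("rsA", "rsB", "rsC"), chrom = "1",
      pos = c(1000L, 2000L, 25000000L),
      a1 = "A", a2 = "G", maf = 0.2, block = c(1L, 1L, 2L)),
    n_ref = 503L), class = "ld_reference")
  ss <- as_summary_stats(data.table::data.table(
    snp_id = c("rsA", "rsB", "rsC"), chrom = "1",
    pos = c(1000L, 2000L, 25000000L), a1 = "A", a2 = "G", maf = 0.2,
    beta = 0.1, se = 0.01, p = c(1e-8, 1e-6, 1e-6), n = 1e4))
  kept <- select_instruments(ss, panel)
  expect_setequal(kept, c("rsA", "rsC"))  # rsB clumped away; rsC beyond LD
  expect_warning(select_instruments(ss[p > 1e-3], panel), "candidates")
})

test_that("clumping equals a brute-force oracle and ignores row order", {
  ld <- .shared_ld
  set.seed(71)
  for (rep in 1:20) {
    take <- sort(sample(nrow(ld$snp_index), 50))
    idx <- ld$snp_index[take]
    ss <- as_summary_stats(data.table::data.table(
      snp_id = idx$snp_id, chrom = idx$chrom, pos = idx$pos,
      a1 = idx$a1, a2 = idx$a2, maf = idx$maf,
      beta = 0.1, se = 0.01, p = runif(50, 1e-10, 1e-4), n = 1e4))
    got <- select_instruments(ss, ld)
    r2_fun <- function(i, j) ld_submatrix(ld, c(i, j))[1, 2]^2
    want <- bf_clump(as.data.frame(ss), r2_fun, 1e-5, 0.001, 10e6)
    expect_identical(got, want)
    shuffled <- ss[sample(nrow(ss))]
    expect_identical(select_instruments(shuffled, ld), got)
  }
})

test_that("the outcome-association filter applies the Bonferroni bound", {
  out_ss <- as_summary_stats(data.table::data.table(
    snp_id = paste0("rs", 1:10), chrom = "1", pos = 1:10 * 1000L,
    a1 = "A", a2 = "G", maf = 0.2, beta = 0.01, se = 0.01,
    p = c(1e-10, rep(0.5, 9)), n = 1e4))
  ids <- paste0("rs", 1:10)
  kept <- filter_outcome_associated(ids, out_ss, alpha = 0.05)
  expect_setequal(kept, paste0("rs", 2:10))  # 1e-10 < 0.05/10
  all_mild <- data.table::copy(out_ss)[, p := 0.5]
  expect_setequal(filter_outcome_associated(ids, all_mild, 0.05), ids)
  # brute force on random p
  set.seed(72)
  pr <- runif(10, 1e-4, 1)
  rnd <- data.table::copy(out_ss)[, p := pr]
  expect_setequal(filter_outcome_associated(ids, rnd, 0.05),
                  ids[pr >= 0.05 / 10])
})

test_that("IVW reduces to exact special cases", {
  inst1 <- data.table::data.table(snp_id = "rs1", bx = 0.2, sx = 0.02,
                                  by = 0.06, sy = 0.02, maf = 0.2)
  single <- ivw(inst1, allow_single = TRUE)
  expect_equal(single$beta, 0.3)
  expect_equal(single$se, 0.02 / 0.2)
  expect_error(ivw(inst1), "at least 2")

  same <- data.table::data.table(snp_id = paste0("rs", 1:5), bx = 0.1,
                                 sx = 0.01, by = 0.025, sy = 0.03, maf = 0.3)
  expect_equal(ivw(same)$beta, 0.25)

  # equal weights: IVW equals the plain mean of ratios
  set.seed(73)
  eq <- data.table::data.table(snp_id = paste0("rs", 1:8), bx = 0.2, sx = 0.02,
                               by = rnorm(8, 0.05, 0.02), sy = 0.04, maf = 0.3)
  expect_equal(ivw(eq)$beta, mean(eq$by / eq$bx))
})

test_that("weighted median hits order statistics and resists invalid instruments", {
  same <- data.table::data.table(snp_id = paste0("rs", 1:4), bx = 0.1,
                                 sx = 0.01, by = 0.03, sy = 0.02, maf = 0.2)
  expect_equal(weighted_median(same, n_boot = 0)$beta, 0.3)

  odd <- data.table::data.table(snp_id = paste0("rs", 1:5), bx = 0.1, sx = 0.01,
                                by = c(0.01, 0.05, 0.03, 0.02, 0.04), sy = 0.02,
                                maf = 0.2)
  expect_equal(weighted_median(odd, n_boot = 0)$beta, 0.3)  # middle ratio

  # 30% invalid with large directional offsets: closer to truth than IVW
  closer <- vapply(1:100, function(s) {
    d <- simulate_mr_dataset(60, architecture_spec(mr = list(beta_xy = 0.2)),
                             seed = 900 + s)
    inst <- d$instruments
    inst$by[1:18] <- inst$by[1:18] + 0.5
    abs(weighted_median(inst, n_boot = 0)$beta - 0.2) <
      abs(ivw(inst)$beta - 0.2)
  }, logical(1))
  expect_gte(mean(closer), 0.8)
})

test_that("MR-Egger interpolates two points and matches constrained IVW", {
  two <- data.table::data.table(snp_id = c("rs1", "rs2"), bx = c(0.1, 0.3),
                                sx = 0.01, by = c(0.05, 0.11), sy = 0.02,
                                maf = 0.2)
  line <- mr_egger(two, min_instruments = 2L)
  expect_equal(line$beta, (0.11 - 0.05) / (0.3 - 0.1))
  expect_equal(line$egger_intercept, 0.05 - line$beta * 0.1)

  # with intercept constrained to zero, the WLS slope is fixed-effect IVW
  set.seed(74)
  inst <- data.table::data.table(snp_id = paste0("rs", 1:20),
                                 bx = abs(rnorm(20, 0.2, 0.05)), sx = 0.02,
                                 by = rnorm(20, 0.04, 0.02),
                                 sy = runif(20, 0.01, 0.05), maf = 0.25)
  wls0 <- stats::lm(by ~ bx - 1, data = inst, weights = 1 / inst$sy^2)
  expect_equal(ivw(inst, random_effects = FALSE)$beta,
               unname(stats::coef(wls0)[1]), tolerance = 1e-12)

  # intercept p-values are uniform without pleiotropy
  ps <- vapply(1:60, function(s) {
    d <- simulate_mr_dataset(50, architecture_spec(mr = list(beta_xy = 0.2)),
                             seed = 1000 + s)
    mr_egger(d$instruments)$egger_intercept_p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.001)
})

test_that("instrument strength diagnostics follow their formulas", {
  inst <- data.table::data.table(snp_id = c("rs1", "rs2"), bx = c(0, 1),
                                 sx = c(0.1, 0.5), by = 0, sy = 1,
                                 maf = c(0.2, 0.5))
  s <- instrument_strength(inst)
  expect_equal(s$min_f, 0)
  expect_equal(s$mean_f, mean(c(0, 4)))
  expect_equal(s$total_r2, 0 + 2 * 0.5 * 0.5 * 1)
  set.seed(75)
  rnd <- data.table::data.table(snp_id = paste0("rs", 1:7),
                                bx = rnorm(7, 0.1, 0.05), sx = runif(7, 0.01, 0.05),
                                by = 0, sy = 1, maf = runif(7, 0.05, 0.5))
  s2 <- instrument_strength(rnd)
  expect_equal(s2$total_r2, sum(2 * rnd$maf * (1 - rnd$maf) * rnd$bx^2))
  expect_equal(s2$min_f, min((rnd$bx / rnd$sx)^2))
})

test_that("the MR screen flags a planted causal direction and only that one", {
  design <- enumerate_mr_design(character(0), c("A", "B"))
  n_seeds <- 20L
  fwd_sig <- logical(n_seeds); rev_null <- logical(n_seeds)
  for (s in seq_len(n_seeds)) {
    sim <- simulate_mr_trait_pair(.shared_ld, beta_xy = 0.3, seed = 80L + s)
    ss <- list(A = sim$ss_x, B = sim$ss_y)
    scr <- mr_screen(design, ss, .shared_ld, seed = 80L + s)
    ivw_rows <- scr[scr$method == "ivw"]
    fwd <- ivw_rows[ivw_rows$exposure == "A"]
    rev <- ivw_rows[ivw_rows$exposure == "B"]
    fwd_sig[s] <- fwd$significant && fwd$beta > 0
    rev_null[s] <- !rev$significant
    if (s == 1L) {
      expect_setequal(scr$method[scr$exposure == "A"],
                      c("ivw", "weighted_median", "egger"))
      expect_true(all(scr$min_f[scr$exposure == "A"] > 10))
    }
  }
  expect_true(all(fwd_sig))
  # the reverse cell is a true null: its false-positive rate stays within
  # 3 binomial SEs of the nominal 5% leak that BH over two tests allows
  expect_lte(mean(!rev_null), 0.05 + 3 * sqrt(0.05 * 0.95 / n_seeds))

  expect_equal(nrow(mr_screen(enumerate_mr_design(character(0), character(0)),
                              ss, .shared_ld)), 0L)
})
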