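#' Run code with a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state, so that
#' every generator in the package is deterministic given its `seed` argument
#' without clobbering the session RNG.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Simulate a block-diagonal LD reference panel
#'
#' Builds an LD reference of AR(1) correlation blocks: within a block
#' `r[j,k] = rho_ar1^|j-k|`, across blocks the correlation is exactly zero.
#' The AR(1) form is always positive definite and has a closed form, which
#' makes eigenvalue-based null distributions easy to reason about. Blocks are
#' laid out on surrogate chromosomes (20 blocks per chromosome) with SNPs
#' spaced 5 kb apart, and each SNP gets an rs-style identifier, a
#' non-palindromic allele pair, and a MAF drawn uniformly from `maf_range`.
#'
#' @param n_blocks number of LD blocks.
#' @param block_size SNPs per block.
#' @param rho_ar1 AR(1) correlation parameter in `[0, 1)`: a scalar applied
#'   to every block, or a length-2 range from which each block's parameter is
#'   drawn uniformly (the default), mimicking the heterogeneity of LD
#'   strength along a real genome and giving the LD scores genuine spread.
#' @param maf_range length-2 vector of MAF bounds.
#' @param seed integer seed.
#' @param blocks_per_chrom blocks per surrogate chromosome.
#' @return an object of class `ld_reference`: a list with `blocks` (list of
#'   correlation matrices), `snp_index` (`data.table` of snp_id, chrom, pos,
#'   a1, a2, maf, block), and `n_ref` (nominal reference-panel sample size).
#' @export
simulate_ld_reference <- function(n_blocks = 20L, block_size = 50L,
                                  rho_ar1 = c(0.2, 0.9),
                                  maf_range = c(0.05, 0.5), seed = 1L,
                                  blocks_per_chrom = 20L) {
  if (any(rho_ar1 < 0) || any(rho_ar1 >= 1)) stop("rho_ar1 must be in [0, 1)")
  with_seed(seed, {
    rho_b <- if (length(rho_ar1) == 1L) rep(rho_ar1, n_blocks)
             else stats::runif(n_blocks, rho_ar1[1], rho_ar1[2])
    d <- abs(outer(seq_len(block_size), seq_len(block_size), "-"))
    blocks <- lapply(rho_b, function(r) r ^ d)
    m <- n_blocks * block_size

    block_of <- rep(seq_len(n_blocks), each = block_size)
    chrom <- as.character((block_of - 1L) %/% blocks_per_chrom + 1L)
    block_in_chrom <- (block_of - 1L) %% blocks_per_chrom
    within <- (seq_len(m) - 1L) %% block_size
    pos <- as.integer(block_in_chrom * 500000L + within * 5000L + 1L)

    allele_pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                          c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
    pick <- sample.int(nrow(allele_pairs), m, replace = TRUE)
    snp_index <- data.table::data.table(
      snp_id = paste0("rs", seq_len(m)),
      chrom = chrom, pos = pos,
      a1 = allele_pairs[pick, 1L], a2 = allele_pairs[pick, 2L],
      maf = stats::runif(m, maf_range[1], maf_range[2]),
      block = block_of
    )
    structure(list(blocks = blocks, snp_index = snp_index, n_ref = 503L),
              class = "ld_reference")
  })
}

#' Tile an LD reference with gene annotations
#'
#' Carves each LD block into consecutive non-overlapping genes of
#' `snps_per_gene` SNPs each, so that every gene's SNPs fall inside a single
#' block and the gene-level causal truth of the simulator is unambiguous.
#'
#' @param ld an `ld_reference`.
#' @param snps_per_gene SNPs per gene; must divide the block size.
#' @return a gene-annotation `data.table` (`gene_id, chrom, start, end`).
#' @export
simulate_gene_annotation <- function(ld, snps_per_gene = 10L) {
  idx <- ld$snp_index
  per_block <- split(seq_len(nrow(idx)), idx$block)
  rows <- lapply(seq_along(per_block), function(b) {
    ii <- per_block[[b]]
    starts <- seq(1L, length(ii), by = snps_per_gene)
    data.table::data.table(
      gene_id = sprintf("gene_b%d_%d", b, seq_along(starts)),
      chrom = idx$chrom[ii[1L]],
      start = idx$pos[ii[starts]],
      end = idx$pos[ii[pmin(starts + snps_per_gene - 1L, length(ii))]]
    )
  })
  data.table::rbindlist(rows)
}

#' Specify a simulated multi-trait genetic architecture
#'
#' Collects the truths of a simulation run: per-trait SNP heritability and
#' GWAS sample size, the proportion of causal genes, an exchangeable genetic
#' correlation, the null Z correlation induced by sample overlap
#' (`rho * Ns / sqrt(N1 * N2)` in the overlapping-samples model), and the
#' causal-effect settings for the Mendelian randomization generator.
#'
#' Genetic correlation is induced by a set of causal genes shared across
#' traits: a fraction `min(1, 2|rg|)` of each trait's causal genes is shared,
#' with cross-trait SNP-effect correlation `rg / fraction`, which yields a
#' genome-wide genetic correlation of `rg`. Within a causal gene, SNP effects
#' are drawn independently by default (`gene_share_w = 0`): gene-level causal
#' status is defined by gene membership, and independent effects keep the
#' summary statistics inside the LD score regression model. A positive
#' `gene_share_w` mixes in a gene-level shared effect component; note that
#' such cross-SNP effect covariance is aligned with local LD and inflates
#' chi-squares beyond the LD-score regressor, so heritability estimates are
#' biased upward under it — useful for demonstrations, not calibration.
#'
#' @param n_traits number of traits.
#' @param h2 per-trait SNP heritability, recycled to `n_traits`.
#' @param n per-trait GWAS sample size, recycled.
#' @param prop_causal_genes proportion of genes that are causal per trait.
#' @param rg exchangeable pairwise genetic correlation.
#' @param overlap_rho expected correlation of null Z-statistics from sample
#'   overlap.
#' @param gene_share_w weight of the gene-level shared effect component.
#' @param mr list of MR-generator truths: `beta_xy` (causal effect),
#'   `pleiotropy_sd` (SD of balanced horizontal pleiotropy),
#'   `directional` (constant added to instrument-outcome effects on the
#'   exposure-increasing orientation), `sigma_x` (SD of true
#'   instrument-exposure effects), `se_x`, `se_y` (standard errors of the
#'   instrument effect estimates), and `min_f` (instruments are drawn
#'   conditional on a true F statistic above this bound, emulating the
#'   relevance assumption of a significance-selected instrument set;
#'   default 20, matching the observed per-trait minimum-F range of about
#'   21 to 27 in instrument sets selected this way).
#' @return a validated list of class `architecture_spec`.
#' @export
architecture_spec <- function(n_traits = 2L, h2 = 0.3, n = 50000,
                              prop_causal_genes = 0.2, rg = 0,
                              overlap_rho = 0, gene_share_w = 0,
                              mr = list()) {
  h2 <- rep_len(h2, n_traits); n <- rep_len(n, n_traits)
  stopifnot(all(h2 >= 0), all(h2 < 1), all(n > 0),
            prop_causal_genes > 0, prop_causal_genes <= 1,
            abs(rg) <= 1, abs(overlap_rho) < 1,
            gene_share_w >= 0, gene_share_w <= 1)
  f_share <- if (rg == 0) 0 else min(1, 2 * abs(rg))
  c_eff <- if (f_share > 0) rg / f_share else 0
  if (n_traits > 2L && c_eff < -1 / (n_traits - 1))
    stop("implied effect-correlation matrix is not positive semidefinite")
  mr_defaults <- list(beta_xy = 0, pleiotropy_sd = 0, directional = 0,
                      sigma_x = 0.1, se_x = 0.02, se_y = 0.02, min_f = 20)
  mr_defaults[names(mr)] <- mr
  structure(list(n_traits = as.integer(n_traits), h2 = h2, n = n,
                 prop_causal_genes = prop_causal_genes, rg = rg,
                 overlap_rho = overlap_rho, gene_share_w = gene_share_w,
                 f_share = f_share, c_eff = c_eff, mr = mr_defaults),
            class = "architecture_spec")
}

# equicorrelated K x K matrix
.equicorr <- function(k, rho) {
  m <- matrix(rho, k, k); diag(m) <- 1; m
}

#' Simulate GWAS summary statistics for several traits under block LD
#'
#' Draws, per LD block, joint Z-statistics for all traits from a multivariate
#' normal with mean `sqrt(N_k) * R %*% beta_k` (the standard non-centrality of
#' marginal association tests under LD), per-trait covariance `R`, and
#' cross-trait covariance `overlap_rho * R`. Standardized SNP effects are
#' drawn gene-wise for the causal genes of each trait and rescaled so the
#' realized standardized-scale heritability equals `h2` exactly; allelic-scale
#' estimates are emitted as `beta_hat = z * se` with
#' `se = 1/sqrt(2 n maf (1-maf))`.
#'
#' @param ld an `ld_reference`.
#' @param annot gene annotation over the same SNPs (see
#'   [simulate_gene_annotation()]).
#' @param arch an `architecture_spec`.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return a list with `sumstats` (list of `summary_stats`, one per trait) and
#'   `truth` (causal gene flags, true standardized effects, realized h2, rg).
#' @export
simulate_summary_multi <- function(ld, annot, arch, seed = 1L) {
  stopifnot(inherits(ld, "ld_reference"), inherits(arch, "architecture_spec"))
  idx <- ld$snp_index
  m <- nrow(idx)
  K <- arch$n_traits
  gene_snps <- map_snps_to_genes(
    data.table::data.table(snp_id = idx$snp_id, chrom = idx$chrom, pos = idx$pos),
    annot)
  genes <- unique(gene_snps$gene_id)
  G <- length(genes)

  with_seed(seed, {
    n_causal <- max(1L, round(arch$prop_causal_genes * G))
    n_shared <- round(arch$f_share * n_causal)
    shared_genes <- sample(genes, n_shared)
    pool <- setdiff(genes, shared_genes)
    specific <- vector("list", K)
    for (k in seq_len(K)) {
      take <- min(n_causal - n_shared, length(pool))
      specific[[k]] <- if (take > 0) sample(pool, take) else character(0)
      pool <- setdiff(pool, specific[[k]])
    }
    causal_flags <- matrix(FALSE, G, K, dimnames = list(genes, NULL))
    causal_flags[shared_genes, ] <- TRUE
    for (k in seq_len(K)) causal_flags[specific[[k]], k] <- TRUE

    # standardized per-SNP effects, unit variance within causal genes
    C_eff <- .equicorr(K, arch$c_eff)
    U_eff <- chol(C_eff)
    w <- arch$gene_share_w
    beta_std <- matrix(0, m, K)
    snp_of_gene <- split(match(gene_snps$snp_id, idx$snp_id), gene_snps$gene_id)
    for (g in shared_genes) {
      jj <- snp_of_gene[[g]]
      u <- drop(stats::rnorm(K) %*% U_eff)
      e <- matrix(stats::rnorm(length(jj) * K), length(jj), K) %*% U_eff
      beta_std[jj, ] <- beta_std[jj, ] +
        sqrt(w) * matrix(u, length(jj), K, byrow = TRUE) + sqrt(1 - w) * e
    }
    for (k in seq_len(K)) {
      for (g in specific[[k]]) {
        jj <- snp_of_gene[[g]]
        beta_std[jj, k] <- sqrt(w) * stats::rnorm(1) +
          sqrt(1 - w) * stats::rnorm(length(jj))
      }
    }
    for (k in seq_len(K)) {
      tot <- sum(beta_std[, k]^2)
      beta_std[, k] <- if (tot > 0 && arch$h2[k] > 0)
        beta_std[, k] * sqrt(arch$h2[k] / tot) else 0
    }

    # joint Z per block: mean sqrt(N) R beta, covariance kron(C_overlap, R)
    C_ov <- .equicorr(K, arch$overlap_rho)
    U_ov <- chol(C_ov)
    z <- matrix(0, m, K)
    sqn <- sqrt(arch$n)
    for (b in seq_along(ld$blocks)) {
      jj <- which(idx$block == b)
      R <- ld$blocks[[b]]
      L <- t(chol(R))
      mu <- R %*% beta_std[jj, , drop = FALSE] %*% diag(sqn, K)
      eps <- matrix(stats::rnorm(length(jj) * K), length(jj), K) %*% U_ov
      z[jj, ] <- mu + L %*% eps
    }

    se <- 1 / sqrt(2 * outer(idx$maf * (1 - idx$maf), arch$n))
    sumstats <- lapply(seq_len(K), function(k) {
      as_summary_stats(data.table::data.table(
        snp_id = idx$snp_id, chrom = idx$chrom, pos = idx$pos,
        a1 = idx$a1, a2 = idx$a2, maf = idx$maf,
        beta = z[, k] * se[, k], se = se[, k],
        p = pmax(2 * stats::pnorm(-abs(z[, k])), 1e-300), n = arch$n[k]))
    })
    truth <- list(causal_flags = causal_flags, beta_std = beta_std,
                  h2 = arch$h2, rg = arch$rg, overlap_rho = arch$overlap_rho,
                  shared_genes = shared_genes, specific_genes = specific)
    list(sumstats = sumstats, truth = truth)
  })
}

#' Simulate a pair of trait summary statistics
#'
#' Two-trait convenience wrapper around [simulate_summary_multi()].
#'
#' @inheritParams simulate_summary_multi
#' @return a list with `ss1`, `ss2` (each `summary_stats`) and `truth`.
#' @export
simulate_summary_pair <- function(ld, annot, arch, seed = 1L) {
  stopifnot(arch$n_traits == 2L)
  sim <- simulate_summary_multi(ld, annot, arch, seed)
  list(ss1 = sim$sumstats[[1L]], ss2 = sim$sumstats[[2L]], truth = sim$truth)
}

#' Simulate a causally linked pair of traits for the MR screen
#'
#' Builds genome-wide summary statistics for an exposure and an outcome with
#' a planted causal effect `beta_xy` (on the standardized scale): the
#' exposure carries strong effects at one SNP in each of
#' `n_instruments_x` randomly chosen LD blocks, the outcome inherits
#' `beta_xy` times the exposure's standardized effects (mediated, or
#' vertical, pleiotropy) plus its own strong effects at `n_instruments_y`
#' SNPs in other blocks. Z-statistics are drawn per block around
#' `sqrt(N) R beta` with covariance `R`. The outcome-specific loci are what
#' make the reverse direction null once the outcome-association filter has
#' removed the mediated loci from the reverse instrument set.
#'
#' @param ld an `ld_reference`.
#' @param beta_xy true causal effect of exposure on outcome (standardized
#'   scale).
#' @param n_instruments_x,n_instruments_y number of instrument loci for the
#'   exposure and of outcome-specific loci.
#' @param n1,n2 GWAS sample sizes.
#' @param z_range magnitude range of instrument non-centrality (uniform).
#' @param seed integer seed.
#' @return a list with `ss_x`, `ss_y` (`summary_stats`) and `truth`
#'   (instrument ids per trait and `beta_xy`).
#' @export
simulate_mr_trait_pair <- function(ld, beta_xy = 0, n_instruments_x = 30L,
                                   n_instruments_y = 30L, n1 = 1e5, n2 = 1e5,
                                   z_range = c(8, 14), seed = 1L) {
  idx <- ld$snp_index
  m <- nrow(idx)
  n_blocks <- length(ld$blocks)
  stopifnot(n_instruments_x + n_instruments_y <= n_blocks)
  with_seed(seed, {
    blocks_x <- sample.int(n_blocks, n_instruments_x)
    blocks_y <- sample(setdiff(seq_len(n_blocks), blocks_x), n_instruments_y)
    pick_snp <- function(b) {
      jj <- which(idx$block == b)
      jj[sample.int(length(jj), 1L)]
    }
    snp_x <- vapply(blocks_x, pick_snp, integer(1))
    snp_y <- vapply(blocks_y, pick_snp, integer(1))

    lam <- function(k) stats::runif(k, z_range[1], z_range[2]) *
      sample(c(-1, 1), k, replace = TRUE)
    bx_std <- numeric(m); bx_std[snp_x] <- lam(n_instruments_x) / sqrt(n1)
    by_own <- numeric(m); by_own[snp_y] <- lam(n_instruments_y) / sqrt(n2)
    by_std <- beta_xy * bx_std + by_own

    z <- matrix(0, m, 2)
    for (b in seq_len(n_blocks)) {
      jj <- which(idx$block == b)
      R <- ld$blocks[[b]]
      L <- t(chol(R))
      z[jj, 1] <- sqrt(n1) * R %*% bx_std[jj] + L %*% stats::rnorm(length(jj))
      z[jj, 2] <- sqrt(n2) * R %*% by_std[jj] + L %*% stats::rnorm(length(jj))
    }
    mk <- function(zk, nk) as_summary_stats(data.table::data.table(
      snp_id = idx$snp_id, chrom = idx$chrom, pos = idx$pos,
      a1 = idx$a1, a2 = idx$a2, maf = idx$maf,
      beta = zk / sqrt(2 * nk * idx$maf * (1 - idx$maf)),
      se = 1 / sqrt(2 * nk * idx$maf * (1 - idx$maf)),
      p = pmax(2 * stats::pnorm(-abs(zk)), 1e-300), n = nk))
    list(ss_x = mk(z[, 1], n1), ss_y = mk(z[, 2], n2),
         truth = list(beta_xy = beta_xy,
                      instruments_x = idx$snp_id[snp_x],
                      instruments_y = idx$snp_id[snp_y]))
  })
}

#' Simulate a two-sample Mendelian randomization instrument table
#'
#' True instrument-exposure effects are drawn normal with SD `mr$sigma_x`;
#' instrument-outcome effects are `beta_xy * b_x + alpha_j + directional *
#' sign(b_x)`, with `alpha_j ~ N(0, pleiotropy_sd^2)` the balanced
#' horizontal-pleiotropy component and `directional` a constant shift on the
#' exposure-increasing allele orientation — the orientation in which the
#' MR-Egger intercept is defined; a constant applied in an arbitrary allele
#' coding would cancel on re-orientation. Observed effects add estimation
#' noise at the stated standard errors.
#'
#' @param n_instruments number of instruments (at least 3).
#' @param arch an `architecture_spec` whose `mr` element holds the truths.
#' @param seed integer seed.
#' @return a list with `instruments` (a `data.table` with
#'   `snp_id, bx, sx, by, sy, maf`) and `truth`.
#' @export
simulate_mr_dataset <- function(n_instruments, arch, seed = 1L) {
  stopifnot(n_instruments >= 3L)
  p <- arch$mr
  with_seed(seed, {
    bx_true <- stats::rnorm(n_instruments, 0, p$sigma_x)
    # relevance: resample until every true F = (bx/se_x)^2 clears min_f
    bound <- sqrt(p$min_f) * p$se_x
    while (any(weak <- abs(bx_true) < bound))
      bx_true[weak] <- stats::rnorm(sum(weak), 0, p$sigma_x)
    alpha <- if (p$pleiotropy_sd > 0)
      stats::rnorm(n_instruments, 0, p$pleiotropy_sd) else numeric(n_instruments)
    by_true <- p$beta_xy * bx_true + alpha + p$directional * sign(bx_true)
    inst <- data.table::data.table(
      snp_id = paste0("rs", seq_len(n_instruments)),
      bx = bx_true + stats::rnorm(n_instruments, 0, p$se_x),
      sx = p$se_x,
      by = by_true + stats::rnorm(n_instruments, 0, p$se_y),
      sy = p$se_y,
      maf = stats::runif(n_instruments, 0.05, 0.5)
    )
    list(instruments = inst,
         truth = list(beta_xy = p$beta_xy, pleiotropy_sd = p$pleiotropy_sd,
                      directional = p$directional, bx_true = bx_true))
  })
}
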