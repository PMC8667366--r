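#' Estimate the null correlation of gene Z-statistics between two traits
#'
#' Pearson correlation of the genome-wide gene Z vectors after excluding
#' genes with `min(p1, p2) < trim_p`, so that genuinely associated genes do
#' not inflate the estimate of the correlation induced by sample overlap.
#'
#' @param z1_vec,z2_vec gene Z-statistics for the two traits, same genes,
#'   same order.
#' @param p1_vec,p2_vec matching gene p-values (used only for trimming);
#'   defaults derive them from the Z-statistics.
#' @param trim_p trimming threshold on `min(p1, p2)`.
#' @return the estimated null Z correlation (scalar).
#' @export
estimate_z_correlation <- function(z1_vec, z2_vec,
                                   p1_vec = 2 * stats::pnorm(-abs(z1_vec)),
                                   p2_vec = 2 * stats::pnorm(-abs(z2_vec)),
                                   trim_p = 1e-4) {
  stopifnot(length(z1_vec) == length(z2_vec))
  keep <- pmin(p1_vec, p2_vec) >= trim_p
  if (sum(keep) < 50)
    warning("fewer than 50 genes after trimming; rho_z estimate is unstable")
  stats::cor(z1_vec[keep], z2_vec[keep])
}

#' De-correlate a pair of Z-statistics
#'
#' Applies the symmetric inverse square root of `R = [[1, rho], [rho, 1]]` to
#' the Z pair, removing the null correlation induced by sample overlap before
#' the composite-null product test. The transform is symmetric in the two
#' traits and reduces to the identity at `rho = 0`.
#'
#' @param z1,z2 gene Z-statistics (vectors, same length).
#' @param rho_z null Z correlation; `|rho_z| >= 0.99` is rejected.
#' @return a list with de-correlated `z1`, `z2`.
#' @export
decorrelate_z <- function(z1, z2, rho_z) {
  if (abs(rho_z) >= 0.99)
    stop("|rho_z| >= 0.99: traits too entangled to de-correlate")
  # R^(-1/2) = P diag(1/sqrt(eig)) P' with eigenvectors (1,1)/sqrt2, (1,-1)/sqrt2
  a <- 1 / sqrt(1 + rho_z); b <- 1 / sqrt(1 - rho_z)
  c1 <- (a + b) / 2; c2 <- (a - b) / 2
  list(z1 = c1 * z1 + c2 * z2, z2 = c2 * z1 + c1 * z2)
}

#' Two-sided tail of the product of two independent zero-mean normals
#'
#' `P(|X * Y| >= |t|)` for independent `X ~ N(0, s1^2)`, `Y ~ N(0, s2^2)`.
#' The product-normal density is `K0(|w| / (s1 s2)) / (pi s1 s2)` with `K0`
#' the modified Bessel function of the second kind; by the scaling identity
#' the general case reduces to `s1 = s2 = 1` at `t / (s1 s2)`. The tail
#' integral is evaluated with exponentially scaled Bessel values so it stays
#' accurate far into the tail.
#'
#' @param t observed product statistic (vectorized).
#' @param s1,s2 standard deviations of the two factors (> 0).
#' @param abs_tol absolute tolerance of the quadrature.
#' @return `P(|XY| >= |t|)`, same length as `t`.
#' @export
product_normal_tail <- function(t, s1 = 1, s2 = 1, abs_tol = 1e-13) {
  stopifnot(s1 > 0, s2 > 0)
  if (any(!is.finite(t))) stop("t must be finite")
  vapply(abs(t) / (s1 * s2), .pn_tail_std, numeric(1), abs_tol = abs_tol)
}

# P(|W| >= t) for W the product of two independent standard normals, t >= 0:
#   2/pi * int_t^Inf K0(w) dw, computed as 2/pi * exp(-t) * int_0^Inf
#   K0s(t+v) exp(-v) dv with K0s the exponentially scaled Bessel function.
.pn_tail_std <- function(t, abs_tol = 1e-13) {
  if (t == 0) return(1)
  f <- function(v) besselK(t + v, 0, expon.scaled = TRUE) * exp(-v)
  val <- stats::integrate(f, 0, Inf, abs.tol = abs_tol,
                          subdivisions = 1000L)$value
  lp <- log(2 / pi) - t + log(val)
  min(exp(lp), 1)
}

#' Variance of gene Z-statistics for one trait
#'
#' The marginal variance of the genome-wide gene Z vector, floored at 1; this
#' captures the polygenic dispersion of an associated trait and parameterizes
#' the one-trait-associated sub-nulls of the composite-null test.
#'
#' @param z_vec genome-wide gene Z-statistics (at least 50 genes).
#' @param exclude_p accepted for interface stability; the estimator uses all
#'   genes.
#' @return the variance, `>= 1`.
#' @export
estimate_sigma_sq <- function(z_vec, exclude_p = NULL) {
  if (length(z_vec) < 50) stop("need at least 50 genes to estimate sigma^2")
  max(1, stats::var(z_vec))
}

#' Composite-null pleiotropy test on a pair of de-correlated Z-statistics
#'
#' The composite null of non-pleiotropy is the union of three sub-nulls:
#' H00 (neither trait associated), H10 and H01 (exactly one associated). The
#' test statistic is the product `T = z1 * z2`; each sub-null p-value is the
#' product-normal tail with the corresponding factor variances (1 under a
#' null trait, `sigma^2 >= 1` under an associated one), and the
#' intersection-union p-value is their maximum, rejecting only when every
#' sub-null is rejected — i.e. in favor of H11, association with both traits.
#'
#' @param z1,z2 de-correlated gene Z-statistics (vectorized, same length).
#' @param sigma1_sq,sigma2_sq marginal Z variances of the two traits
#'   (each `>= 1`).
#' @return a `data.table` with columns `T`, `p00`, `p10`, `p01`, `p_placo`.
#' @export
placo_test <- function(z1, z2, sigma1_sq = 1, sigma2_sq = 1) {
  stopifnot(length(z1) == length(z2))
  if (sigma1_sq < 1 || sigma2_sq < 1) stop("sigma^2 must be >= 1")
  T_stat <- z1 * z2
  p00 <- product_normal_tail(T_stat, 1, 1)
  p10 <- if (sigma1_sq == 1) p00 else product_normal_tail(T_stat, sqrt(sigma1_sq), 1)
  p01 <- if (sigma2_sq == 1) p00 else product_normal_tail(T_stat, 1, sqrt(sigma2_sq))
  data.table::data.table(T = T_stat, p00 = p00, p10 = p10, p01 = p01,
                         p_placo = pmax(p00, p10, p01))
}

#' Benjamini-Hochberg step-up adjusted q-values
#'
#' @param p_vec p-values in `(0, 1]`.
#' @return BH-adjusted q-values, same order as the input.
#' @export
fdr_bh <- function(p_vec) stats::p.adjust(p_vec, method = "BH")

#' Benjamini-Yekutieli step-up adjusted q-values
#'
#' Includes the harmonic-number factor, valid under arbitrary dependence;
#' used for per-SNP heterogeneity p-values where local LD makes neighboring
#' tests dependent.
#'
#' @inheritParams fdr_bh
#' @return BY-adjusted q-values.
#' @export
fdr_by <- function(p_vec) stats::p.adjust(p_vec, method = "BY")

#' Direct-FDR comparator: genes significant in both traits separately
#'
#' @param p1_vec,p2_vec named gene p-value vectors (same genes, same order;
#'   names taken from `p1_vec` or indices when unnamed).
#' @param alpha FDR level.
#' @return character vector of genes with BH q-value below `alpha` in both
#'   traits.
#' @export
direct_fdr_method <- function(p1_vec, p2_vec, alpha = 0.05) {
  ids <- if (!is.null(names(p1_vec))) names(p1_vec) else as.character(seq_along(p1_vec))
  ids[fdr_bh(p1_vec) < alpha & fdr_bh(p2_vec) < alpha]
}

#' Maximum-P comparator: BH on the per-gene maximum of the two p-values
#'
#' @inheritParams direct_fdr_method
#' @return character vector of genes whose max-p BH q-value is below `alpha`.
#' @export
max_p_method <- function(p1_vec, p2_vec, alpha = 0.05) {
  ids <- if (!is.null(names(p1_vec))) names(p1_vec) else as.character(seq_along(p1_vec))
  ids[fdr_bh(pmax(p1_vec, p2_vec)) < alpha]
}

#' Likelihood-ratio test for overall pleiotropy between two traits
#'
#' Fits, by EM, a four-component mixture over the paired gene p-values with
#' components (null,null), (alt,null), (null,alt), (alt,alt); the null
#' density is uniform and each trait's alternative density is
#' `Beta(alpha, 1)`, i.e. `alpha * p^(alpha-1)` with `0 < alpha < 1`. The
#' full model has free mixing proportions; the constrained model imposes
#' independence of the two association indicators,
#' `pi11 = (pi10 + pi11) * (pi01 + pi11)`. Twice the log-likelihood gap is
#' referred to the chi-square(1) upper tail.
#'
#' @param p1_vec,p2_vec gene p-values for the two traits (at least 500
#'   genes).
#' @param max_iter EM iteration cap.
#' @param tol relative log-likelihood convergence tolerance.
#' @return a list with `lrt_stat`, `p_lrt`, and `mixture_params` (the full
#'   and constrained fits).
#' @export
overall_pleiotropy_lrt <- function(p1_vec, p2_vec, max_iter = 5000L, tol = 1e-9) {
  stopifnot(length(p1_vec) == length(p2_vec))
  if (length(p1_vec) < 500) stop("need at least 500 genes for the LRT")
  p1 <- pmin(pmax(p1_vec, 1e-300), 1)
  p2 <- pmin(pmax(p2_vec, 1e-300), 1)
  full <- .pleio_mix_em(p1, p2, constrained = FALSE, max_iter = max_iter, tol = tol)
  cons <- .pleio_mix_em(p1, p2, constrained = TRUE, max_iter = max_iter, tol = tol)
  stat <- max(0, 2 * (full$loglik - cons$loglik))
  list(lrt_stat = stat,
       p_lrt = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       mixture_params = list(full = full, constrained = cons))
}

.pleio_mix_em <- function(p1, p2, constrained, max_iter, tol) {
  n <- length(p1)
  lp1 <- log(p1); lp2 <- log(p2)
  a1 <- 0.3; a2 <- 0.3
  if (constrained) { m1 <- 0.2; m2 <- 0.2 } else pi <- c(0.7, 0.1, 0.1, 0.1)
  clamp_a <- function(a) min(max(a, 1e-4), 1 - 1e-6)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    f1 <- a1 * p1^(a1 - 1); f2 <- a2 * p2^(a2 - 1)
    if (constrained) pi <- c((1 - m1) * (1 - m2), m1 * (1 - m2),
                             (1 - m1) * m2, m1 * m2)
    dens <- cbind(pi[1], pi[2] * f1, pi[3] * f2, pi[4] * f1 * f2)
    rs <- rowSums(dens)
    ll <- sum(log(rs))
    r <- dens / rs
    w1 <- r[, 2] + r[, 4]; w2 <- r[, 3] + r[, 4]
    if (constrained) {
      m1 <- min(max(mean(w1), 1e-6), 1 - 1e-6)
      m2 <- min(max(mean(w2), 1e-6), 1 - 1e-6)
    } else {
      pi <- pmax(colMeans(r), 1e-10); pi <- pi / sum(pi)
    }
    d1 <- sum(w1 * lp1); d2 <- sum(w2 * lp2)
    a1 <- clamp_a(if (d1 < 0) -sum(w1) / d1 else 1 - 1e-6)
    a2 <- clamp_a(if (d2 < 0) -sum(w2) / d2 else 1 - 1e-6)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  if (it == max_iter && abs(ll - ll_old) >= tol * (abs(ll_old) + 1))
    warning("pleiotropy-mixture EM hit the iteration cap (",
            max_iter, "); loglik gap ", signif(abs(ll - ll_old), 3))
  # final log-likelihood at the returned parameters
  f1 <- a1 * p1^(a1 - 1); f2 <- a2 * p2^(a2 - 1)
  if (constrained) pi <- c((1 - m1) * (1 - m2), m1 * (1 - m2),
                           (1 - m1) * m2, m1 * m2)
  ll <- sum(log(pi[1] + pi[2] * f1 + pi[3] * f2 + pi[4] * f1 * f2))
  list(pi = pi, alpha = c(a1, a2), loglik = ll, iterations = it)
}

#' Pearson correlation of per-SNP effect sizes within a gene
#'
#' Requires both traits harmonized to the same effect allele and at least 3
#' SNPs; returns `NA` (flagged, not computed) below that.
#'
#' @param betas1,betas2 per-SNP effect sizes in the gene for the two traits.
#' @return Pearson r, or `NA_real_` for genes with fewer than 3 SNPs.
#' @export
effect_correlation <- function(betas1, betas2) {
  stopifnot(length(betas1) == length(betas2))
  if (length(betas1) < 3) return(NA_real_)
  stats::cor(betas1, betas2)
}

#' Cochran's Q heterogeneity test between two effect estimates
#'
#' For two estimates the inverse-variance-weighted Q collapses to
#' `(beta1 - beta2)^2 / (se1^2 + se2^2)`, referred to the chi-square(1) upper
#' tail. Vectorized over SNPs.
#'
#' @param beta1,se1,beta2,se2 effect sizes and standard errors per SNP.
#' @return a `data.table` with columns `Q` and `p_het`.
#' @export
cochran_q <- function(beta1, se1, beta2, se2) {
  Q <- (beta1 - beta2)^2 / (se1^2 + se2^2)
  data.table::data.table(Q = Q,
                         p_het = stats::pchisq(Q, df = 1, lower.tail = FALSE))
}

#' Hypergeometric enrichment of a query gene list in a gene set
#'
#' Upper-tail hypergeometric probability of observing at least the realized
#' overlap between `query_genes` and `gene_set` when drawing
#' `length(query intersect background)` genes from `background`.
#'
#' @param query_genes character vector of query genes.
#' @param gene_set character vector defining the set.
#' @param background character vector of all eligible genes.
#' @return a list with `overlap` and `p_enrich`.
#' @export
hypergeometric_enrichment <- function(query_genes, gene_set, background) {
  query <- intersect(unique(query_genes), background)
  set <- intersect(unique(gene_set), background)
  overlap <- length(intersect(query, set))
  # P(X >= overlap), X ~ Hypergeom(|set| successes, N - |set|, |query| draws)
  p <- stats::phyper(overlap - 1, length(set),
                     length(background) - length(set), length(query),
                     lower.tail = FALSE)
  list(overlap = overlap, p_enrich = min(p, 1))
}

#' Full pleiotropy analysis for one trait pair
#'
#' Estimates the null Z correlation, de-correlates the gene Z-statistics,
#' estimates each trait's marginal Z variance, runs the composite-null
#' product test gene by gene, and applies BH FDR within the pair. When SNP
#' effect tables are supplied it also characterizes each significant gene by
#' the Pearson correlation of per-SNP effects and the fraction of SNPs with
#' heterogeneous effects (Cochran's Q with Benjamini-Yekutieli adjustment
#' across all SNPs of the pair's significant genes).
#'
#' @param tab1,tab2 per-trait gene association tables from
#'   [gene_assoc_table()], aligned by `gene_id` internally.
#' @param ss1,ss2 optional harmonized `summary_stats` for the SNP-level
#'   characterization.
#' @param annot gene annotation (required with `ss1`/`ss2`).
#' @param alpha FDR level used for `n_significant` and gene detail.
#' @param trim_p trimming threshold for the null-correlation estimate.
#' @return a list with `genes` (per-gene `data.table`: `gene_id, z1, z2, T,
#'   p_placo, q_fdr`, plus `r_effect, prop_heterogeneous` when SNP data are
#'   given), and `pair` (one-row summary: `rho_z, sigma1_sq, sigma2_sq,
#'   n_genes, n_significant, lrt_stat, p_lrt`).
#' @export
placo_pair_analysis <- function(tab1, tab2, ss1 = NULL, ss2 = NULL,
                                annot = NULL, alpha = 0.05, trim_p = 1e-4) {
  common <- intersect(tab1$gene_id, tab2$gene_id)
  t1 <- tab1[match(common, tab1$gene_id)]
  t2 <- tab2[match(common, tab2$gene_id)]
  rho_z <- estimate_z_correlation(t1$z, t2$z, t1$p, t2$p, trim_p = trim_p)
  dz <- decorrelate_z(t1$z, t2$z, rho_z)
  s1 <- estimate_sigma_sq(dz$z1)
  s2 <- estimate_sigma_sq(dz$z2)
  pl <- placo_test(dz$z1, dz$z2, s1, s2)
  genes <- data.table::data.table(gene_id = common, z1 = dz$z1, z2 = dz$z2,
                                  p1 = t1$p, p2 = t2$p,
                                  T = pl$T, p_placo = pl$p_placo,
                                  q_fdr = fdr_bh(pl$p_placo))
  lrt <- if (length(common) >= 500) overall_pleiotropy_lrt(t1$p, t2$p)
         else {
           warning("fewer than 500 genes; overall-pleiotropy LRT skipped")
           list(lrt_stat = NA_real_, p_lrt = NA_real_)
         }

  sig <- genes$gene_id[genes$q_fdr < alpha]
  if (!is.null(ss1) && !is.null(ss2) && !is.null(annot) && length(sig)) {
    detail <- pleio_gene_detail(sig, ss1, ss2, annot)
    genes <- merge(genes, detail, by = "gene_id", all.x = TRUE, sort = FALSE)
  }
  pair <- data.table::data.table(rho_z = rho_z, sigma1_sq = s1, sigma2_sq = s2,
                                 n_genes = length(common),
                                 n_significant = length(sig),
                                 lrt_stat = lrt$lrt_stat, p_lrt = lrt$p_lrt)
  list(genes = genes, pair = pair)
}

#' SNP-level characterization of pleiotropic genes
#'
#' For each listed gene: Pearson correlation of per-SNP effect sizes across
#' the two traits (NA below 3 SNPs) and, after Benjamini-Yekutieli adjustment
#' of per-SNP Cochran's Q p-values across all SNPs of all listed genes, the
#' proportion of the gene's SNPs with heterogeneous effects at `alpha`.
#'
#' @param gene_ids genes to characterize.
#' @param ss1,ss2 harmonized `summary_stats`.
#' @param annot gene annotation.
#' @param alpha significance level on the BY-adjusted heterogeneity q-values.
#' @return a `data.table` with `gene_id, r_effect, prop_heterogeneous`.
#' @export
pleio_gene_detail <- function(gene_ids, ss1, ss2, annot, alpha = 0.05) {
  hits <- map_snps_to_genes(ss1, annot[annot$gene_id %in% gene_ids, ])
  ss1 <- data.table::as.data.table(ss1); ss2 <- data.table::as.data.table(ss2)
  i1 <- match(hits$snp_id, ss1$snp_id); i2 <- match(hits$snp_id, ss2$snp_id)
  keep <- !is.na(i1) & !is.na(i2)
  hits <- hits[keep]; i1 <- i1[keep]; i2 <- i2[keep]
  het <- cochran_q(ss1$beta[i1], ss1$se[i1], ss2$beta[i2], ss2$se[i2])
  q_by <- fdr_by(het$p_het)
  dt <- data.table::data.table(gene_id = hits$gene_id,
                               b1 = ss1$beta[i1], b2 = ss2$beta[i2],
                               het_sig = q_by < alpha)
  dt[, .(r_effect = effect_correlation(b1, b2),
         prop_heterogeneous = mean(het_sig)), by = gene_id]
}

#' Summaries of shared pleiotropic genes across trait pairs
#'
#' From a named list of per-pair results (names like `"T1|T2"`), computes the
#' per-pair count of significant genes, the number of distinct traits each
#' significant gene is linked to, and a gene-by-trait sign table from the
#' de-correlated Z-statistics.
#'
#' @param pair_results named list; each element either the list returned by
#'   [placo_pair_analysis()] or its `genes` table.
#' @param alpha FDR level defining significance.
#' @return a list with `pair_counts`, `gene_trait_counts`, and `sign_table`.
#' @export
shared_gene_summary <- function(pair_results, alpha = 0.05) {
  empty <- list(
    pair_counts = data.table::data.table(pair = character(), n_significant = integer()),
    gene_trait_counts = data.table::data.table(gene_id = character(), n_traits = integer()),
    sign_table = data.table::data.table(gene_id = character(), trait = character(),
                                        sign = integer()))
  if (!length(pair_results)) return(empty)
  tabs <- lapply(pair_results, function(x) if (is.list(x) && !is.null(x$genes)) x$genes else x)
  pair_counts <- data.table::data.table(
    pair = names(tabs),
    n_significant = vapply(tabs, function(g) sum(g$q_fdr < alpha), integer(1)))

  links <- data.table::rbindlist(lapply(names(tabs), function(nm) {
    g <- tabs[[nm]]
    sig <- g[g$q_fdr < alpha]
    if (!nrow(sig)) return(NULL)
    traits <- strsplit(nm, "|", fixed = TRUE)[[1L]]
    data.table::rbindlist(list(
      data.table::data.table(gene_id = sig$gene_id, trait = traits[1L],
                             sign = ifelse(sig$z1 >= 0, 1L, -1L)),
      data.table::data.table(gene_id = sig$gene_id, trait = traits[2L],
                             sign = ifelse(sig$z2 >= 0, 1L, -1L))))
  }))
  if (is.null(links) || !nrow(links)) return(empty)
  sign_table <- unique(links)
  gene_trait_counts <- sign_table[, .(n_traits = data.table::uniqueN(trait)),
                                  by = gene_id]
  list(pair_counts = pair_counts, gene_trait_counts = gene_trait_counts,
       sign_table = sign_table)
}
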