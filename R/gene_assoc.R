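#' Map SNPs to genes by position
#'
#' Assigns every SNP to every gene whose `[start, end]` interval (1-based,
#' inclusive on both ends) contains its position; a SNP inside two overlapping
#' genes is assigned to both. Genes with no SNPs are omitted. An optional
#' symmetric window pads gene boundaries (default 0 bp, i.e. strictly within
#' the gene body).
#'
#' @param ss a table with at least `snp_id, chrom, pos`.
#' @param annot gene annotation (`gene_id, chrom, start, end`).
#' @param window_bp symmetric padding added to both gene ends, in bp.
#' @return a `data.table` with columns `gene_id, snp_id, pos`.
#' @export
map_snps_to_genes <- function(ss, annot, window_bp = 0L) {
  ss <- data.table::as.data.table(ss)
  a <- data.table::as.data.table(annot)
  a <- data.table::data.table(gene_id = a$gene_id, chrom = as.character(a$chrom),
                              lo = a$start - window_bp, hi = a$end + window_bp)
  s <- data.table::data.table(snp_id = ss$snp_id, chrom = as.character(ss$chrom),
                              lo = ss$pos, hi = ss$pos, pos = ss$pos)
  hits <- s[a, on = .(chrom, lo >= lo, hi <= hi), nomatch = NULL,
            .(gene_id = i.gene_id, snp_id = x.snp_id, pos = x.pos)]
  data.table::setorder(hits, gene_id, pos)
  hits[]
}

#' Tail probability of a weighted sum of chi-square variables (Imhof)
#'
#' Computes `P(sum_i lambda_i * chisq_1 >= q)` by numerical inversion of the
#' characteristic function (Imhof's integral), with a Satterthwaite
#' moment-matching fallback when the integral fails to converge or returns a
#' value at the integration noise floor.
#'
#' @param q observed statistic.
#' @param lambda eigenvalue weights (non-negative after clipping).
#' @param abs_tol absolute tolerance of the quadrature.
#' @return upper-tail probability in `(0, 1]`.
#' @keywords internal
imhof_tail <- function(q, lambda, abs_tol = 1e-12) {
  lambda <- lambda[lambda > 0]
  if (!length(lambda)) stop("no positive eigenvalue weights")
  # equal weights collapse to an exact chi-square tail
  if (diff(range(lambda)) < 1e-10 * max(lambda))
    return(min(max(stats::pchisq(q / max(lambda), df = length(lambda),
                                 lower.tail = FALSE), 1e-300), 1))
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    sin(theta) / (u * rho)
  }
  satterthwaite <- function() {
    s1 <- sum(lambda); s2 <- sum(lambda^2)
    p <- stats::pchisq(q * s1 / s2, df = s1^2 / s2, lower.tail = FALSE)
    min(max(p, 1e-300), 1)
  }
  val <- tryCatch(
    stats::integrate(integrand, 0, Inf, abs.tol = abs_tol,
                     subdivisions = 2000L, stop.on.error = TRUE)$value,
    error = function(e) NA_real_)
  if (is.na(val)) return(satterthwaite())
  p <- 0.5 + val / pi
  # below the quadrature noise floor the moment-matched tail is more reliable
  if (p < 1e-10) p <- satterthwaite()
  min(max(p, 1e-300), 1)
}

#' Gene-level association test: sum of SNP chi-squares under local LD
#'
#' Aggregates a gene's SNP Z-statistics into `S = sum(z^2)`, whose null
#' distribution under local LD is the weighted sum `sum_i lambda_i * chisq_1`
#' with `lambda_i` the eigenvalues of the gene's SNP correlation matrix. The
#' tail probability is computed with [imhof_tail()].
#'
#' @param z_vec SNP Z-statistics for the gene (length >= 1).
#' @param R_sub the matching SNP-SNP correlation submatrix.
#' @return a list with `S` (the statistic), `p` (gene p-value), and
#'   `n_snps`.
#' @export
gene_test_sum_chisq <- function(z_vec, R_sub) {
  m <- length(z_vec)
  stopifnot(m >= 1L)
  R_sub <- as.matrix(R_sub)
  stopifnot(nrow(R_sub) == m, ncol(R_sub) == m)
  S <- sum(z_vec^2)
  lambda <- eigen(R_sub, symmetric = TRUE, only.values = TRUE)$values
  if (any(lambda < -1e-8)) stop("R_sub is not positive semidefinite")
  lambda <- pmax(lambda, 0)
  list(S = S, p = imhof_tail(S, lambda), n_snps = m)
}

#' Direction of a gene's association
#'
#' The gene sign is the sign of the MAF-weighted sum of SNP effect sizes,
#' `sum(beta * maf)`; an exact zero resolves to `+1`.
#'
#' @param betas per-SNP effect sizes within the gene.
#' @param mafs matching minor-allele frequencies.
#' @return `+1` or `-1`.
#' @export
gene_sign <- function(betas, mafs) {
  stopifnot(length(betas) >= 1L, length(betas) == length(mafs))
  if (sum(betas * mafs) >= 0) 1 else -1
}

#' Convert a gene p-value and sign to a signed Z-statistic
#'
#' `z = sign * qnorm(1 - p/2)`, with `p` floored at 1e-300 before inversion
#' so the result is always finite.
#'
#' @param p_gene gene p-value in `(0, 1]`; vectorized.
#' @param sign `+1`/`-1`, recycled against `p_gene`.
#' @return signed gene Z-statistic(s).
#' @export
gene_p_to_z <- function(p_gene, sign = 1) {
  if (any(p_gene <= 0 | p_gene > 1)) stop("p_gene must lie in (0, 1]")
  if (!all(sign %in% c(-1, 1))) stop("sign must be +1 or -1")
  p <- pmax(p_gene, 1e-300)
  sign * stats::qnorm(p / 2, lower.tail = FALSE)
}

#' Extract the LD correlation submatrix for a set of SNPs
#'
#' Builds the (block-diagonal) correlation matrix of the requested SNPs from
#' an `ld_reference`; SNPs in different blocks get correlation 0.
#'
#' @param ld an `ld_reference`.
#' @param snp_ids SNP identifiers present in the reference.
#' @return a correlation matrix with rows/columns in `snp_ids` order.
#' @export
ld_submatrix <- function(ld, snp_ids) {
  idx <- match(snp_ids, ld$snp_index$snp_id)
  if (anyNA(idx)) stop("SNP(s) not in the LD reference: ",
                       paste(snp_ids[is.na(idx)], collapse = ", "))
  m <- length(idx)
  R <- matrix(0, m, m)
  blk <- ld$snp_index$block[idx]
  within <- unlist(lapply(split(seq_len(nrow(ld$snp_index)), ld$snp_index$block),
                          seq_along), use.names = FALSE)[idx]
  for (b in unique(blk)) {
    sel <- which(blk == b)
    R[sel, sel] <- ld$blocks[[b]][within[sel], within[sel]]
  }
  diag(R) <- 1
  R
}

#' Per-gene association table for one trait
#'
#' Runs the full gene-level aggregation for one trait: maps SNPs into genes,
#' computes the sum-of-chi-squares p-value against the local LD eigenvalue
#' null, attaches the MAF-weighted effect sign, and converts to a signed gene
#' Z-statistic.
#'
#' @param ss harmonized `summary_stats` for the trait.
#' @param annot gene annotation.
#' @param ld the `ld_reference` supplying local correlation.
#' @param window_bp gene-boundary padding passed to [map_snps_to_genes()].
#' @return a `data.table` with one row per gene: `gene_id, chrom, start, end,
#'   n_snps, S, p, sign, z`.
#' @export
gene_assoc_table <- function(ss, annot, ld, window_bp = 0L) {
  hits <- map_snps_to_genes(ss, annot, window_bp)
  ss <- data.table::as.data.table(ss)
  a <- data.table::as.data.table(annot)
  rows <- lapply(split(hits$snp_id, hits$gene_id), function(ids) {
    sub <- ss[match(ids, ss$snp_id)]
    R <- ld_submatrix(ld, ids)
    tst <- gene_test_sum_chisq(sub$z, R)
    sgn <- gene_sign(sub$beta, sub$maf)
    data.table::data.table(n_snps = tst$n_snps, S = tst$S, p = tst$p,
                           sign = sgn, z = gene_p_to_z(tst$p, sgn))
  })
  out <- data.table::rbindlist(rows, idcol = "gene_id")
  out <- merge(a[, .(gene_id, chrom, start, end)], out, by = "gene_id")
  data.table::setorder(out, chrom, start)
  out[]
}
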