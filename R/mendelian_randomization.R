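#' Enumerate the Mendelian randomization design
#'
#' One-sided pairs from each childhood-onset trait to every adulthood-onset
#' trait, plus all ordered pairs among adulthood-onset traits (the
#' bidirectional screen). With 2 childhood and 10 adulthood traits this gives
#' 20 + 90 = 110 exposure-outcome relationships.
#'
#' @param childhood_traits,adulthood_traits character vectors of trait ids.
#' @return a `data.table` with columns `exposure, outcome, design`
#'   (`"childhood"` or `"adulthood"`), deduplicated, in deterministic order.
#' @export
enumerate_mr_design <- function(childhood_traits, adulthood_traits) {
  child <- if (length(childhood_traits) && length(adulthood_traits))
    data.table::CJ(exposure = childhood_traits, outcome = adulthood_traits,
                   sorted = FALSE)[, design := "childhood"] else NULL
  adult <- if (length(adulthood_traits) >= 2L)
    data.table::CJ(exposure = adulthood_traits, outcome = adulthood_traits,
                   sorted = FALSE)[exposure != outcome][, design := "adulthood"] else NULL
  out <- data.table::rbindlist(list(child, adult))
  if (is.null(out) || !nrow(out))
    return(data.table::data.table(exposure = character(), outcome = character(),
                                  design = character()))
  out <- unique(out, by = c("exposure", "outcome"))
  data.table::setorder(out, design, exposure, outcome)
  out[]
}

#' Select approximately independent instruments by greedy LD clumping
#'
#' Candidates are SNPs with `p < p_thresh`, ranked by ascending p-value (ties
#' broken by position, then id). The top-ranked SNP is kept and all remaining
#' candidates within `dist_bp` of it AND with squared correlation above
#' `r2_thresh` against it are discarded; the procedure repeats on what is
#' left. Cross-block correlations are exactly zero in a block LD reference.
#'
#' @param exposure_ss `summary_stats` of the exposure trait.
#' @param ld an `ld_reference`.
#' @param p_thresh instrument significance cutoff (default 1e-5).
#' @param r2_thresh LD pruning threshold (default 0.001).
#' @param dist_bp physical distance threshold in bp (default 10 Mb).
#' @return character vector of selected SNP ids (may be empty, with a
#'   warning).
#' @export
select_instruments <- function(exposure_ss, ld, p_thresh = 1e-5,
                               r2_thresh = 0.001, dist_bp = 10e6) {
  ss <- data.table::as.data.table(exposure_ss)
  cand <- ss[ss$p < p_thresh]
  if (!nrow(cand)) {
    warning("no instrument candidates below p_thresh")
    return(character(0))
  }
  data.table::setorder(cand, p, pos, snp_id)
  kept <- character(0)
  while (nrow(cand)) {
    top <- cand[1L]
    kept <- c(kept, top$snp_id)
    same_chr <- cand$chrom == top$chrom
    near <- same_chr & abs(cand$pos - top$pos) <= dist_bp
    r2 <- numeric(nrow(cand))
    if (any(near)) {
      R <- ld_submatrix(ld, c(top$snp_id, cand$snp_id[near]))
      r2[near] <- R[1L, -1L]^2
    }
    drop <- near & r2 > r2_thresh
    drop[1L] <- TRUE  # the index SNP itself leaves the candidate pool
    cand <- cand[!drop]
  }
  kept
}

#' Drop instruments associated with the outcome
#'
#' Removes instruments whose outcome p-value falls below the Bonferroni
#' threshold `alpha / n_instruments`, guarding the screen against reverse
#' association and linkage with outcome loci.
#'
#' @param instrument_ids selected instrument SNP ids.
#' @param outcome_ss `summary_stats` of the outcome trait.
#' @param alpha nominal level before the Bonferroni division.
#' @return the filtered id vector.
#' @export
filter_outcome_associated <- function(instrument_ids, outcome_ss, alpha = 0.05) {
  if (!length(instrument_ids)) return(instrument_ids)
  p_out <- outcome_ss$p[match(instrument_ids, outcome_ss$snp_id)]
  thresh <- alpha / length(instrument_ids)
  instrument_ids[is.na(p_out) | p_out >= thresh]
}

#' Assemble the instrument effect table for one exposure-outcome pair
#'
#' @param instrument_ids SNP ids to use.
#' @param exposure_ss,outcome_ss harmonized `summary_stats` (same effect
#'   allele convention).
#' @return a `data.table` with `snp_id, bx, sx, by, sy, maf, f_stat`.
#' @export
make_mr_instruments <- function(instrument_ids, exposure_ss, outcome_ss) {
  ie <- match(instrument_ids, exposure_ss$snp_id)
  io <- match(instrument_ids, outcome_ss$snp_id)
  keep <- !is.na(ie) & !is.na(io)
  ie <- ie[keep]; io <- io[keep]
  data.table::data.table(
    snp_id = instrument_ids[keep],
    bx = exposure_ss$beta[ie], sx = exposure_ss$se[ie],
    by = outcome_ss$beta[io], sy = outcome_ss$se[io],
    maf = exposure_ss$maf[ie],
    f_stat = (exposure_ss$beta[ie] / exposure_ss$se[ie])^2)
}

.mr_result <- function(method, beta, se, n_inst, extra = list()) {
  ci <- beta + c(-1, 1) * 1.96 * se
  out <- data.table::data.table(
    method = method, n_instruments = n_inst, beta = beta, se = se,
    ci_low = ci[1], ci_high = ci[2],
    p = 2 * stats::pnorm(-abs(beta / se)),
    or_point = exp(beta), or_ci_low = exp(ci[1]), or_ci_high = exp(ci[2]))
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out
}

#' Inverse-variance weighted MR estimate
#'
#' Per-SNP ratio estimates `by/bx` combined with weights `bx^2 / sy^2`
#' (first-order weights); the multiplicative random-effects standard error
#' scales the fixed-effect SE by `sqrt(max(1, Q/(J-1)))` with Q the
#' heterogeneity statistic, so overdispersion widens but never narrows the
#' interval. Instruments with `bx = 0` are dropped with a warning.
#'
#' @param instruments table from [make_mr_instruments()] (at least 2 rows,
#'   or 1 with `allow_single`).
#' @param random_effects use the multiplicative random-effects SE (default).
#' @param allow_single permit a single-instrument Wald ratio.
#' @return a one-row `data.table` MR result.
#' @export
ivw <- function(instruments, random_effects = TRUE, allow_single = FALSE) {
  inst <- instruments[instruments$bx != 0]
  if (nrow(inst) < nrow(instruments))
    warning("dropped instrument(s) with bx = 0")
  J <- nrow(inst)
  if (J == 1L && allow_single)
    return(.mr_result("ivw", inst$by / inst$bx, inst$sy / abs(inst$bx), 1L))
  if (J < 2L) stop("IVW needs at least 2 instruments")
  ratio <- inst$by / inst$bx
  w <- inst$bx^2 / inst$sy^2
  beta <- sum(w * ratio) / sum(w)
  Q <- sum(w * (ratio - beta)^2)
  phi <- if (random_effects) max(1, Q / (J - 1)) else 1
  .mr_result("ivw", beta, sqrt(phi / sum(w)), J, list(q_het = Q))
}

#' Weighted-median MR estimate
#'
#' The weighted median of the per-SNP ratio estimates (IVW weights,
#' normalized), consistent when instruments carrying at least half the weight
#' are valid. The standard error comes from a seeded parametric bootstrap of
#' the instrument effects.
#'
#' @inheritParams ivw
#' @param n_boot bootstrap resamples for the SE; `0` skips the bootstrap and
#'   reports `NA` standard errors (point estimate only).
#' @param seed integer seed for the bootstrap.
#' @return a one-row `data.table` MR result.
#' @export
weighted_median <- function(instruments, n_boot = 10000L, seed = 1L) {
  inst <- instruments[instruments$bx != 0]
  if (nrow(inst) < 2L) stop("weighted median needs at least 2 instruments")
  est <- .weighted_median_point(inst$bx, inst$by, inst$sy)
  if (n_boot < 2L)
    return(.mr_result("weighted_median", est, NA_real_, nrow(inst)))
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx_b <- stats::rnorm(nrow(inst), inst$bx, inst$sx)
      by_b <- stats::rnorm(nrow(inst), inst$by, inst$sy)
      .weighted_median_point(bx_b, by_b, inst$sy)
    }, numeric(1))
  })
  .mr_result("weighted_median", est, stats::sd(boot), nrow(inst))
}

# weighted median of by/bx with weights bx^2/sy^2, standard interpolation
# at cumulative weight 1/2
.weighted_median_point <- function(bx, by, sy) {
  ok <- bx != 0
  ratio <- by[ok] / bx[ok]
  w <- bx[ok]^2 / sy[ok]^2
  ord <- order(ratio)
  ratio <- ratio[ord]; w <- w[ord] / sum(w)
  cw <- cumsum(w) - w / 2
  if (cw[1L] >= 0.5) return(ratio[1L])
  k <- max(which(cw < 0.5))
  if (k == length(ratio)) return(ratio[k])
  ratio[k] + (ratio[k + 1L] - ratio[k]) * (0.5 - cw[k]) / (cw[k + 1L] - cw[k])
}

#' MR-Egger regression
#'
#' After orienting every instrument to a non-negative exposure effect
#' (flipping `bx` and `by` jointly), regresses `by` on `bx` by weighted least
#' squares (weights `1/sy^2`) with a free intercept. The slope estimates the
#' causal effect under the InSIDE assumption; the intercept indexes
#' directional pleiotropy. Standard errors carry a multiplicative
#' overdispersion factor floored at 1.
#'
#' @inheritParams ivw
#' @param min_instruments minimum instrument count (3 by default; the
#'   two-point case is exactly interpolating and only useful for checks).
#' @return a one-row `data.table` MR result with `egger_intercept`,
#'   `egger_intercept_se`, `egger_intercept_p`.
#' @export
mr_egger <- function(instruments, min_instruments = 3L) {
  inst <- instruments[instruments$bx != 0]
  J <- nrow(inst)
  if (J < min_instruments) stop("MR-Egger needs at least ", min_instruments,
                                " instruments")
  flip <- inst$bx < 0
  bx <- abs(inst$bx)
  by <- ifelse(flip, -inst$by, inst$by)
  w <- 1 / inst$sy^2
  fit <- stats::lm(by ~ bx, weights = w)
  cf <- summary(fit)$coefficients
  # multiplicative overdispersion, floored so SEs never shrink below WLS
  disp <- max(1, sum(w * stats::residuals(fit)^2) / (J - 2))
  base_sigma2 <- summary(fit)$sigma^2
  scale <- sqrt(disp / base_sigma2)
  se_slope <- cf["bx", "Std. Error"] * scale
  se_icpt <- cf["(Intercept)", "Std. Error"] * scale
  .mr_result("egger", cf["bx", "Estimate"], se_slope, J,
             list(egger_intercept = cf["(Intercept)", "Estimate"],
                  egger_intercept_se = se_icpt,
                  egger_intercept_p = 2 * stats::pnorm(-abs(cf["(Intercept)", "Estimate"] / se_icpt))))
}

#' Instrument strength diagnostics
#'
#' Per-SNP F statistic `(bx/sx)^2` and variance explained
#' `2 maf (1 - maf) bx^2` on the standardized-trait scale.
#'
#' @param instruments table from [make_mr_instruments()].
#' @return a list with `mean_f`, `min_f`, `total_r2`.
#' @export
instrument_strength <- function(instruments) {
  f <- (instruments$bx / instruments$sx)^2
  r2 <- 2 * instruments$maf * (1 - instruments$maf) * instruments$bx^2
  list(mean_f = mean(f), min_f = min(f), total_r2 = sum(r2))
}

#' Run the full Mendelian randomization screen
#'
#' For every exposure-outcome relationship in the design: clump instruments
#' from the exposure, drop outcome-associated ones (Bonferroni within the
#' selected set), and estimate the causal effect by IVW, weighted median, and
#' MR-Egger with strength diagnostics. BH FDR is applied over the IVW
#' p-values across the whole design (jointly by default), and bidirectionally
#' significant pairs are flagged.
#'
#' @param design table from [enumerate_mr_design()].
#' @param sumstats_by_trait named list of harmonized `summary_stats`.
#' @param ld an `ld_reference`.
#' @param p_thresh,r2_thresh,dist_bp clumping parameters.
#' @param bonferroni_alpha level of the outcome-association filter.
#' @param fdr_alpha FDR level for significance flags.
#' @param fdr_scope `"joint"` (over the whole design) or `"per_design"`
#'   (childhood and adulthood analyses corrected separately).
#' @param min_instruments relationships with fewer instruments are reported
#'   with NA estimates.
#' @param seed seed for the weighted-median bootstrap.
#' @return a `data.table` with one row per relationship and method, plus
#'   `q_fdr` (IVW rows), `significant`, and `bidirectional` flags.
#' @export
mr_screen <- function(design, sumstats_by_trait, ld,
                      p_thresh = 1e-5, r2_thresh = 0.001, dist_bp = 10e6,
                      bonferroni_alpha = 0.05, fdr_alpha = 0.05,
                      fdr_scope = c("joint", "per_design"),
                      min_instruments = 3L, seed = 1L) {
  fdr_scope <- match.arg(fdr_scope)
  if (!nrow(design))
    return(data.table::data.table(exposure = character(), outcome = character(),
                                  method = character(), beta = numeric()))
  rows <- lapply(seq_len(nrow(design)), function(i) {
    expo <- design$exposure[i]; outc <- design$outcome[i]
    es <- sumstats_by_trait[[expo]]; os <- sumstats_by_trait[[outc]]
    ids <- suppressWarnings(select_instruments(es, ld, p_thresh, r2_thresh, dist_bp))
    ids <- filter_outcome_associated(ids, os, bonferroni_alpha)
    inst <- make_mr_instruments(ids, es, os)
    meta <- data.table::data.table(exposure = expo, outcome = outc,
                                   design = design$design[i])
    if (nrow(inst) < min_instruments) {
      res <- .mr_result("ivw", NA_real_, NA_real_, nrow(inst))
      return(cbind(meta, res))
    }
    strength <- instrument_strength(inst)
    res <- data.table::rbindlist(list(
      ivw(inst),
      weighted_median(inst, n_boot = 1000L, seed = seed + i),
      mr_egger(inst)), fill = TRUE)
    res$min_f <- strength$min_f
    res$total_r2 <- strength$total_r2
    cbind(meta[rep(1L, nrow(res))], res)
  })
  out <- data.table::rbindlist(rows, fill = TRUE)
  is_ivw <- out$method == "ivw"
  out$q_fdr <- NA_real_
  if (fdr_scope == "joint") {
    out$q_fdr[is_ivw] <- fdr_bh(out$p[is_ivw])
  } else {
    for (d in unique(out$design)) {
      sel <- is_ivw & out$design == d
      out$q_fdr[sel] <- fdr_bh(out$p[sel])
    }
  }
  out$significant <- !is.na(out$q_fdr) & out$q_fdr < fdr_alpha
  sig_pairs <- paste(out$exposure[out$significant], out$outcome[out$significant])
  out$bidirectional <- out$significant &
    paste(out$outcome, out$exposure) %in% sig_pairs
  out[]
}
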