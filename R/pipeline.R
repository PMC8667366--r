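#' Enumerate unordered trait pairs
#'
#' All `n * (n-1) / 2` unordered pairs in deterministic order (pairs of 14
#' traits: 91; of 10: 45).
#'
#' @param traits character vector of trait ids.
#' @return a `data.table` with columns `trait1, trait2`.
#' @export
enumerate_trait_pairs <- function(traits) {
  n <- length(traits)
  if (n < 2L)
    return(data.table::data.table(trait1 = character(), trait2 = character()))
  cmb <- utils::combn(traits, 2L)
  data.table::data.table(trait1 = cmb[1L, ], trait2 = cmb[2L, ])
}

#' Build a validated pipeline run configuration
#'
#' All thresholds default to the analysis' standard settings: FDR level 0.05,
#' instrument cutoff 1e-5, clumping r2 0.001 within 10 Mb, Z-correlation
#' trimming at 1e-4, and Bonferroni level 0.05 for the outcome-association
#' filter.
#'
#' @param traits character vector of trait ids.
#' @param childhood_traits subset of `traits` tagged childhood-onset (used by
#'   the MR design); the rest are adulthood-onset.
#' @param synthetic list of generator settings: `h2`, `n`, `rg`,
#'   `overlap_rho`, `prop_causal_genes`, `n_blocks`, `block_size`,
#'   `rho_ar1`, `snps_per_gene`.
#' @param fdr_alpha,instrument_p,clump_r2,clump_dist,trim_p,bonferroni_alpha
#'   analysis thresholds.
#' @param seed root seed; stage seeds are derived as fixed offsets from it.
#' @param out_dir output directory for the report bundle.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(traits = c("T1", "T2", "T3"),
                            childhood_traits = character(0),
                            synthetic = list(),
                            fdr_alpha = 0.05, instrument_p = 1e-5,
                            clump_r2 = 0.001, clump_dist = 10e6,
                            trim_p = 1e-4, bonferroni_alpha = 0.05,
                            seed = 1L, out_dir = tempfile("pleiogene_run_")) {
  stopifnot(length(traits) >= 2L, all(childhood_traits %in% traits),
            fdr_alpha > 0, fdr_alpha < 1, instrument_p > 0, instrument_p < 1,
            clump_r2 >= 0, clump_r2 <= 1, clump_dist > 0,
            trim_p > 0, trim_p < 1, bonferroni_alpha > 0, bonferroni_alpha <= 1)
  syn_defaults <- list(h2 = 0.3, n = 50000, rg = 0.4, overlap_rho = 0.1,
                       prop_causal_genes = 0.2, n_blocks = 40L,
                       block_size = 50L, rho_ar1 = 0.6, snps_per_gene = 10L)
  syn_defaults[names(synthetic)] <- synthetic
  structure(list(traits = traits, childhood_traits = childhood_traits,
                 synthetic = syn_defaults, fdr_alpha = fdr_alpha,
                 instrument_p = instrument_p, clump_r2 = clump_r2,
                 clump_dist = clump_dist, trim_p = trim_p,
                 bonferroni_alpha = bonferroni_alpha,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

# LD scores restricted to the SNPs of a (QC-filtered) trait, keeping the
# genome-wide M
.align_scores <- function(scores, ld, ss) {
  idx <- match(ss$snp_id, ld$snp_index$snp_id)
  list(ell = scores$ell[idx], M = scores$M)
}

#' Run the full pleiotropy pipeline on synthetic multi-trait data
#'
#' Executes, in order: simulation of an LD reference, gene annotation and
#' per-trait summary statistics; QC and allele harmonization; per-trait gene
#' association tables; the composite-null pleiotropy analysis for every
#' unordered trait pair with shared-gene summaries; LD score regression
#' (per-trait heritability and intercept, pairwise genetic correlation) and
#' hierarchical clustering of the correlation matrix; the bidirectional MR
#' screen; and a report bundle of TSV tables plus a manifest.
#'
#' @param config a `pipeline_config`.
#' @return invisibly, a list with every intermediate object and a `files`
#'   vector of written table paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  syn <- config$synthetic
  K <- length(config$traits)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  ld <- .stage("simulate_ld", simulate_ld_reference(
    n_blocks = syn$n_blocks, block_size = syn$block_size,
    rho_ar1 = syn$rho_ar1, seed = config$seed))
  annot <- .stage("annotation", simulate_gene_annotation(ld, syn$snps_per_gene))
  arch <- architecture_spec(n_traits = K, h2 = syn$h2, n = syn$n,
                            prop_causal_genes = syn$prop_causal_genes,
                            rg = syn$rg, overlap_rho = syn$overlap_rho)
  sim <- .stage("simulate_sumstats",
                simulate_summary_multi(ld, annot, arch, seed = config$seed + 1L))
  sumstats <- stats::setNames(sim$sumstats, config$traits)

  qc <- .stage("qc", lapply(sumstats, function(ss) {
    q <- apply_qc_filters(ss, ld)
    q$ss <- harmonize_alleles(q$ss, ld)
    q
  }))
  sumstats <- lapply(qc, `[[`, "ss")
  qc_report <- data.table::rbindlist(lapply(qc, `[[`, "report"),
                                     idcol = "trait")

  gene_tabs <- .stage("gene_assoc",
                      lapply(sumstats, gene_assoc_table, annot = annot, ld = ld))

  pairs <- enumerate_trait_pairs(config$traits)
  pleio <- .stage("pleiotropy", {
    res <- lapply(seq_len(nrow(pairs)), function(i) {
      t1 <- pairs$trait1[i]; t2 <- pairs$trait2[i]
      placo_pair_analysis(gene_tabs[[t1]], gene_tabs[[t2]],
                          ss1 = sumstats[[t1]], ss2 = sumstats[[t2]],
                          annot = annot, alpha = config$fdr_alpha,
                          trim_p = config$trim_p)
    })
    names(res) <- paste(pairs$trait1, pairs$trait2, sep = "|")
    res
  })
  shared <- shared_gene_summary(pleio, alpha = config$fdr_alpha)

  ldsc <- .stage("ldsc", {
    scores <- compute_ld_scores(ld)
    h2_fits <- lapply(sumstats, function(ss)
      ldsc_h2(ss, .align_scores(scores, ld, ss)))
    rg_mat <- diag(1, K); dimnames(rg_mat) <- list(config$traits, config$traits)
    rg_rows <- lapply(seq_len(nrow(pairs)), function(i) {
      t1 <- pairs$trait1[i]; t2 <- pairs$trait2[i]
      common <- intersect(sumstats[[t1]]$snp_id, sumstats[[t2]]$snp_id)
      s1 <- sumstats[[t1]][match(common, sumstats[[t1]]$snp_id)]
      s2 <- sumstats[[t2]][match(common, sumstats[[t2]]$snp_id)]
      fit <- ldsc_rg(s1, s2, .align_scores(scores, ld, s1))
      rg_mat[t1, t2] <<- rg_mat[t2, t1] <<- fit$rg
      data.table::data.table(trait1 = t1, trait2 = t2, rg = fit$rg,
                             se_rg = fit$se_rg,
                             gcov_intercept = fit$gcov_intercept)
    })
    list(h2 = h2_fits, rg_table = data.table::rbindlist(rg_rows),
         rg_matrix = rg_mat)
  })
  clust <- .stage("cluster",
                  cluster_traits(ldsc$rg_matrix, k = min(3L, K)))

  adulthood <- setdiff(config$traits, config$childhood_traits)
  design <- enumerate_mr_design(config$childhood_traits, adulthood)
  mr <- .stage("mr", mr_screen(design, sumstats, ld,
                               p_thresh = config$instrument_p,
                               r2_thresh = config$clump_r2,
                               dist_bp = config$clump_dist,
                               bonferroni_alpha = config$bonferroni_alpha,
                               fdr_alpha = config$fdr_alpha,
                               seed = config$seed + 2L))

  files <- .stage("report", {
    out <- config$out_dir
    ldsc_tab <- data.table::data.table(
      trait = config$traits,
      h2 = vapply(ldsc$h2, `[[`, numeric(1), "h2"),
      se_h2 = vapply(ldsc$h2, `[[`, numeric(1), "se_h2"),
      intercept = vapply(ldsc$h2, `[[`, numeric(1), "intercept"),
      lambda_gc = vapply(ldsc$h2, `[[`, numeric(1), "lambda_gc"))
    pleio_genes <- data.table::rbindlist(lapply(pleio, `[[`, "genes"),
                                         idcol = "pair", fill = TRUE)
    pleio_pairs <- data.table::rbindlist(lapply(pleio, `[[`, "pair"),
                                         idcol = "pair")
    tabs <- list(qc_report = qc_report, ldsc_traits = ldsc_tab,
                 ldsc_rg = ldsc$rg_table,
                 cluster_labels = data.table::data.table(
                   trait = names(clust$labels), cluster = clust$labels),
                 pleiotropy_genes = pleio_genes,
                 pleiotropy_pairs = pleio_pairs,
                 shared_gene_counts = shared$gene_trait_counts,
                 pair_counts = shared$pair_counts,
                 mr_results = mr)
    paths <- character(0)
    for (nm in names(tabs))
      paths[nm] <- write_pipeline_table(tabs[[nm]],
                                        file.path(out, paste0(nm, ".tsv")))
    manifest <- c(
      paste0("package_version\t", as.character(utils::packageVersion("pleiogene"))),
      paste0("seed\t", config$seed),
      paste0("n_traits\t", K),
      paste0("generated_tables\t", paste(names(tabs), collapse = ",")))
    manifest_path <- file.path(out, "manifest.tsv")
    writeLines(manifest, manifest_path)
    c(paths, manifest = manifest_path)
  })

  invisible(list(config = config, ld = ld, annot = annot, truth = sim$truth,
                 sumstats = sumstats, qc_report = qc_report,
                 gene_tables = gene_tabs, pleiotropy = pleio, shared = shared,
                 ldsc = ldsc, cluster = clust, mr = mr, files = files))
}
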