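#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort.
#
# Builds a block-LD reference panel (100 AR(1) blocks x 50 SNPs with
# heterogeneous per-block LD strength), a gene annotation tiling the panel
# (10 SNPs per gene, 500 genes), and GWAS summary statistics for three
# traits with a shared polygenic architecture (h2 = 0.3, rg = 0.4, 20% of
# genes causal, sample-overlap correlation 0.1). Writes the summary
# statistics in the package's TSV dialect plus the ground truth.

suppressPackageStartupMessages({
  library(pleiogene)
  library(data.table)
})

seed <- 1L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

message("simulating LD reference and gene annotation ...")
ld <- simulate_ld_reference(n_blocks = 100L, block_size = 50L, seed = seed)
annot <- simulate_gene_annotation(ld, snps_per_gene = 10L)
write_pipeline_table(ld$snp_index, file.path(out, "ld_snp_index.tsv"))
write_pipeline_table(annot, file.path(out, "gene_annotation.tsv"))
# later stages rebuild the panel from the same seed rather than reading a
# serialized object; the generator is deterministic

arch <- architecture_spec(n_traits = 3L, h2 = 0.3, n = 5e4,
                          prop_causal_genes = 0.2, rg = 0.4,
                          overlap_rho = 0.1)
message("simulating summary statistics for 3 traits ...")
sim <- simulate_summary_multi(ld, annot, arch, seed = seed + 1L)
traits <- c("T1", "T2", "T3")
for (k in seq_along(traits))
  write_pipeline_table(sim$sumstats[[k]],
                       file.path(out, paste0("sumstats_", traits[k], ".tsv")))

truth <- data.table(gene_id = rownames(sim$truth$causal_flags),
                    sim$truth$causal_flags)
setnames(truth, c("gene_id", paste0("causal_", traits)))
write_pipeline_table(truth, file.path(out, "truth_causal_genes.tsv"))

message(sprintf("wrote %d SNPs x %d traits, %d genes (%d causal per trait, %d shared)",
                nrow(ld$snp_index), length(traits), nrow(annot),
                sum(sim$truth$causal_flags[, 1]),
                length(sim$truth$shared_genes)))
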