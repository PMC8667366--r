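# Shared fixtures, built in code at load time.

# a hand-made four-SNP reference panel on two blocks
tiny_panel <- function() {
  structure(list(
    blocks = list(matrix(c(1, 0.5, 0.5, 1), 2), matrix(c(1, 0.2, 0.2, 1), 2)),
    snp_index = data.table::data.table(
      snp_id = c("rs1", "rs2", "rs3", "rs4"),
      chrom = c("1", "1", "2", "2"),
      pos = c(1000L, 2000L, 1000L, 2000L),
      a1 = c("A", "G", "T", "C"),
      a2 = c("G", "T", "G", "A"),
      maf = c(0.3, 0.2, 0.4, 0.1),
      block = c(1L, 1L, 2L, 2L)),
    n_ref = 503L), class = "ld_reference")
}

# well-formed three-SNP summary statistics matching tiny_panel()
tiny_sumstats <- function() {
  as_summary_stats(data.table::data.table(
    SNP = c("rs1", "rs2", "rs3"), CHR = c("1", "1", "2"),
    BP = c(1000L, 2000L, 1000L),
    A1 = c("A", "G", "T"), A2 = c("G", "T", "G"),
    MAF = c(0.3, 0.2, 0.4), BETA = c(0.1, -0.05, 0.02),
    SE = c(0.02, 0.02, 0.01), P = c(1e-6, 0.012, 0.046), N = 10000))
}

# QC fixture: 3 clean SNPs plus one violation of each filter stage; the
# duplicated id contributes two rows, both dropped. 10 rows, 3 retained.
qc_fixture <- function() {
  clean <- data.table::data.table(
    snp_id = c("rs1", "rs2", "rs3"), chrom = c("1", "1", "2"),
    pos = c(1000L, 2000L, 1000L), a1 = c("A", "G", "T"), a2 = c("G", "T", "G"),
    maf = c(0.3, 0.2, 0.4), beta = 0.01, se = 0.01, p = 0.5, n = 10000)
  bad <- data.table::data.table(
    snp_id = c("rs101", "rs102", "notAnRsId", "rs4", "rs4", "rs105", "rs106"),
    chrom  = c("1", "1", "1", "2", "2", "6", "1"),
    pos    = c(3000L, 4000L, 5000L, 2000L, 2000L, 28500000L, 6000L),
    a1     = c("AT", "A", "A", "C", "C", "A", "A"),
    a2     = c("G", "T", "G", "A", "A", "G", "G"),
    maf    = c(0.3, 0.3, 0.3, 0.1, 0.1, 0.3, 0.005),
    beta = 0.01, se = 0.01, p = 0.5, n = 10000)
  out <- rbind(clean, bad)
  data.table::setattr(out, "class", c("summary_stats", class(out)))
  out
}

# panel that also covers the QC fixture's extra rs ids (rs4 duplicated pair,
# rs101-rs106); alleles chosen so only the intended filters fire
qc_panel <- function() {
  p <- tiny_panel()
  extra <- data.table::data.table(
    snp_id = c("rs101", "rs102", "rs105", "rs106"),
    chrom = c("1", "1", "6", "1"),
    pos = c(3000L, 4000L, 28500000L, 6000L),
    a1 = c("A", "A", "A", "A"), a2 = c("G", "T", "G", "G"),
    maf = c(0.3, 0.3, 0.3, 0.005), block = 2L)
  p$snp_index <- rbind(p$snp_index, extra)
  p
}

# moderate simulated dataset reused across tests (one build per test run)
.shared_ld <- simulate_ld_reference(n_blocks = 100L, block_size = 50L, seed = 42L)
.shared_annot <- simulate_gene_annotation(.shared_ld, 10L)
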