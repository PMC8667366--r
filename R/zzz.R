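.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", "i.gene_id", "x.snp_id", "x.pos", "gene_id", "chrom", "start", "end",
  "snp_id", "pos", "b1", "b2", "het_sig", "trait", "design", "exposure",
  "outcome", "p"
))
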