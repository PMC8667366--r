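#' Read GWAS summary statistics from delimited text
#'
#' Reads a whitespace- or tab-delimited summary-statistics file with a header
#' and returns a validated `data.table` with the standard columns
#' `snp_id, chrom, pos, a1, a2, maf, beta, se, p, n, z`. Column names are
#' resolved case-insensitively against the usual GWAS dialect
#' (`SNP, CHR, BP, A1, A2, FRQ`/`MAF`, `BETA` or `OR`, `SE, P, N`); a
#' `column_map` overrides that resolution for nonstandard headers.
#'
#' When the file carries an odds ratio instead of a beta, the effect is
#' converted by natural log at read time. `z` is derived as `beta/se` when not
#' supplied, and `p` from `z` via the two-sided normal tail when absent.
#'
#' @param path path to the delimited file.
#' @param column_map optional named character vector mapping canonical names
#'   (`snp_id`, `chrom`, `pos`, `a1`, `a2`, `maf`, `beta`, `or`, `se`, `p`,
#'   `n`) to the column names found in the file. Mapping `or` (instead of
#'   `beta`) requests the log-odds conversion.
#' @return a `data.table` of class `summary_stats`.
#' @export
read_summary_stats <- function(path, column_map = NULL) {
  dt <- data.table::fread(path, header = TRUE, data.table = TRUE)
  as_summary_stats(dt, column_map = column_map)
}

# canonical -> accepted header spellings (case-insensitive)
.ss_aliases <- list(
  snp_id = c("snp", "snp_id", "rsid", "rs_id", "markername", "id"),
  chrom  = c("chr", "chrom", "chromosome"),
  pos    = c("bp", "pos", "position", "base_pair_location"),
  a1     = c("a1", "effect_allele", "allele1", "ea"),
  a2     = c("a2", "other_allele", "allele2", "oa", "nea"),
  maf    = c("frq", "maf", "freq", "eaf", "af"),
  beta   = c("beta", "b", "effect"),
  or     = c("or", "odds_ratio"),
  se     = c("se", "stderr", "standard_error"),
  p      = c("p", "pval", "p_value", "pvalue"),
  n      = c("n", "nobs", "sample_size"),
  z      = c("z", "zscore", "z_score")
)

#' Coerce a data frame of association results to validated summary statistics
#'
#' @param dt a data.frame or data.table with per-SNP association results.
#' @inheritParams read_summary_stats
#' @return a `data.table` of class `summary_stats`.
#' @export
as_summary_stats <- function(dt, column_map = NULL) {
  dt <- data.table::as.data.table(dt)
  lower <- tolower(names(dt))
  resolve <- function(canon) {
    if (!is.null(column_map) && canon %in% names(column_map)) {
      hit <- match(tolower(column_map[[canon]]), lower)
      if (is.na(hit)) stop("column_map names '", column_map[[canon]],
                           "' for '", canon, "' but no such column exists")
      return(hit)
    }
    hits <- match(.ss_aliases[[canon]], lower)
    hits <- hits[!is.na(hits)]
    if (length(hits)) hits[1L] else NA_integer_
  }
  idx <- vapply(names(.ss_aliases), resolve, integer(1))

  mandatory <- c("snp_id", "chrom", "pos", "a1", "a2", "maf", "se", "p", "n")
  missing_cols <- mandatory[is.na(idx[mandatory])]
  if (length(missing_cols))
    stop("mandatory column(s) missing: ", paste(missing_cols, collapse = ", "))
  if (is.na(idx["beta"]) && is.na(idx["or"]))
    stop("need an effect column: BETA or OR")

  out <- data.table::data.table(
    snp_id = as.character(dt[[idx["snp_id"]]]),
    chrom  = as.character(dt[[idx["chrom"]]]),
    pos    = as.integer(dt[[idx["pos"]]]),
    a1     = toupper(as.character(dt[[idx["a1"]]])),
    a2     = toupper(as.character(dt[[idx["a2"]]])),
    maf    = as.numeric(dt[[idx["maf"]]]),
    se     = as.numeric(dt[[idx["se"]]]),
    p      = as.numeric(dt[[idx["p"]]]),
    n      = as.numeric(dt[[idx["n"]]])
  )
  out$beta <- if (!is.na(idx["beta"])) as.numeric(dt[[idx["beta"]]])
              else log(as.numeric(dt[[idx["or"]]]))

  for (col in c("pos", "maf", "se", "p", "n", "beta"))
    if (anyNA(out[[col]]))
      stop("non-numeric or missing values in column '", col, "' (row ",
           which(is.na(out[[col]]))[1L], ")")
  if (any(out$se <= 0))
    stop("non-positive SE at row ", which(out$se <= 0)[1L])
  if (any(out$maf <= 0 | out$maf >= 1))
    stop("MAF outside (0,1) at row ", which(out$maf <= 0 | out$maf >= 1)[1L])
  out$maf <- pmin(out$maf, 1 - out$maf)  # fold to minor-allele frequency
  if (any(out$p <= 0 | out$p > 1))
    stop("p-value outside (0,1] at row ", which(out$p <= 0 | out$p > 1)[1L])

  out$z <- if (!is.na(idx["z"])) as.numeric(dt[[idx["z"]]]) else out$beta / out$se
  data.table::setcolorder(out, c("snp_id", "chrom", "pos", "a1", "a2", "maf",
                                 "beta", "se", "p", "n", "z"))
  data.table::setattr(out, "class", c("summary_stats", class(out)))
  out[]
}

#' Read a gene annotation table
#'
#' BED-like TSV with columns `gene_id, chrom, start, end`; coordinates are
#' 1-based and inclusive on both ends.
#'
#' @param path path to the annotation file.
#' @return a `data.table` with columns `gene_id, chrom, start, end`.
#' @export
read_gene_annotation <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = TRUE,
                          colClasses = list(character = c("gene_id", "chrom")))
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(dt)))
  dt$start <- as.integer(dt$start); dt$end <- as.integer(dt$end)
  if (any(dt$start > dt$end)) stop("gene with start > end")
  if (anyDuplicated(dt$gene_id)) stop("duplicated gene_id in annotation")
  dt[]
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

.is_palindromic <- function(a1, a2) {
  ok <- a1 %in% names(.complement) & a2 %in% names(.complement)
  out <- rep(FALSE, length(a1))
  out[ok] <- unname(.complement[a1[ok]]) == a2[ok]
  out
}

.is_biallelic_snp <- function(a1, a2) {
  nchar(a1) == 1L & nchar(a2) == 1L &
    a1 %in% names(.complement) & a2 %in% names(.complement) & a1 != a2
}

#' Quality-control filtering of summary statistics
#'
#' Applies, in a fixed order, the five standard filters: (i) drop
#' non-biallelic SNPs and strand-ambiguous (palindromic A/T, C/G) SNPs;
#' (ii) drop SNPs without an rs-style identifier (`rs` followed by digits);
#' (iii) drop duplicated identifiers (all copies, since the correct record
#' cannot be told apart) and SNPs absent from the LD reference panel or with
#' alleles incompatible with it; (iv) drop SNPs in the MHC region
#' (chr6:28.5-33.5 Mb, boundaries inclusive); (v) keep SNPs with MAF > 0.01.
#' Each SNP is attributed to the first filter it fails, so the per-filter
#' counts in the report always reconcile with the input count.
#'
#' @param ss a `summary_stats` table.
#' @param panel an `ld_reference` (see [simulate_ld_reference()]), used for
#'   panel membership and allele-compatibility checks.
#' @return a list with elements `ss` (the filtered table) and `report`
#'   (a one-row `data.table` of per-filter counts).
#' @export
apply_qc_filters <- function(ss, panel) {
  idx <- panel$snp_index
  n_in <- nrow(ss)
  stage <- rep(NA_character_, n_in)

  bad_allele <- !.is_biallelic_snp(ss$a1, ss$a2)
  palin <- !bad_allele & .is_palindromic(ss$a1, ss$a2)
  stage[bad_allele] <- "non_biallelic"
  stage[palin] <- "strand_ambiguous"

  no_rs <- is.na(stage) & !grepl("^rs[0-9]+$", ss$snp_id)
  stage[no_rs] <- "no_rsid"

  dup_ids <- unique(ss$snp_id[duplicated(ss$snp_id)])
  m <- match(ss$snp_id, idx$snp_id)
  compatible <- !is.na(m) & (
    (ss$a1 == idx$a1[m] & ss$a2 == idx$a2[m]) |
    (ss$a1 == idx$a2[m] & ss$a2 == idx$a1[m]) |
    (unname(.complement[ss$a1]) == idx$a1[m] & unname(.complement[ss$a2]) == idx$a2[m]) |
    (unname(.complement[ss$a1]) == idx$a2[m] & unname(.complement[ss$a2]) == idx$a1[m])
  )
  compatible[is.na(compatible)] <- FALSE
  bad_panel <- is.na(stage) & (ss$snp_id %in% dup_ids | !compatible)
  stage[bad_panel] <- "duplicated_or_unmatched"

  mhc <- is.na(stage) & ss$chrom %in% c("6", "chr6") &
    ss$pos >= 28.5e6 & ss$pos <= 33.5e6
  stage[mhc] <- "mhc_excluded"

  low_maf <- is.na(stage) & ss$maf <= 0.01
  stage[low_maf] <- "low_maf"

  keep <- is.na(stage)
  report <- data.table::data.table(
    input = n_in,
    non_biallelic = sum(stage == "non_biallelic", na.rm = TRUE),
    strand_ambiguous = sum(stage == "strand_ambiguous", na.rm = TRUE),
    no_rsid = sum(stage == "no_rsid", na.rm = TRUE),
    duplicated_or_unmatched = sum(stage == "duplicated_or_unmatched", na.rm = TRUE),
    mhc_excluded = sum(stage == "mhc_excluded", na.rm = TRUE),
    low_maf = sum(stage == "low_maf", na.rm = TRUE),
    retained = sum(keep)
  )
  if (report$retained == 0L) warning("no SNPs retained after QC")
  list(ss = ss[keep], report = report)
}

#' Harmonize summary statistics to the reference panel's allele convention
#'
#' SNPs whose `(a1, a2)` are swapped relative to the panel (directly or as
#' strand complements) have their `beta` and `z` signs flipped and their
#' allele frequency reflected, so that every trait ends up on the panel's
#' effect-allele convention; records whose alleles cannot be reconciled with
#' the panel are dropped. Applying the function twice is a no-op.
#'
#' @inheritParams apply_qc_filters
#' @return a harmonized `summary_stats` table with alleles set to the panel's.
#' @export
harmonize_alleles <- function(ss, panel) {
  idx <- panel$snp_index
  m <- match(ss$snp_id, idx$snp_id)
  in_panel <- !is.na(m)

  p1 <- idx$a1[m]; p2 <- idx$a2[m]
  c1 <- unname(.complement[ss$a1]); c2 <- unname(.complement[ss$a2])
  same <- in_panel & ((ss$a1 == p1 & ss$a2 == p2) | (c1 == p1 & c2 == p2))
  swap <- in_panel & !same & ((ss$a1 == p2 & ss$a2 == p1) | (c1 == p2 & c2 == p1))

  dropped <- sum(!(same | swap))
  if (dropped > 0)
    warning(dropped, " SNP(s) dropped during harmonization (alleles irreconcilable)")

  out <- ss[same | swap]
  m <- m[same | swap]
  flip <- swap[same | swap]
  out$beta[flip] <- -out$beta[flip]
  out$z[flip] <- -out$z[flip]
  maf_flipped <- 1 - out$maf[flip]
  out$maf[flip] <- pmin(maf_flipped, 1 - maf_flipped)
  out$a1 <- idx$a1[m]
  out$a2 <- idx$a2[m]
  out[]
}

#' Write a pipeline table as TSV
#'
#' Floats are written with 6 significant digits; used for every table the
#' pipeline emits.
#'
#' @param x a data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_table <- function(x, path) {
  x <- data.table::as.data.table(x)
  num <- vapply(x, is.double, logical(1))
  for (col in names(x)[num]) data.table::set(x, j = col, value = signif(x[[col]], 6))
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}
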