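CONSEQUENCES <- c("nonsynonymous", "stop_gain", "stop_loss", "splicing",
                  "synonymous", "other", "unknown")
DELETERIOUS <- c("nonsynonymous", "stop_gain", "stop_loss", "splicing")
SOURCES <- c("M_FNA", "M_P_FNA", "M_P_TR_BF", "M_P_TR")

VCALL_COLS <- c("chrom", "pos", "ref", "alt", "alt_reads", "depth", "maf",
                "strand_bias", "p_binomial_adj", "z_stat", "p_z_adj",
                "log10_p_z_adj", "consequence", "source", "filters")

#' An empty table of variant calls
#'
#' Variant calls are plain data frames with a fixed column set: coordinates
#' and alleles, supporting reads and total Q30 depth, mutant allele fraction
#' (`maf = alt_reads / depth`, total-depth denominator), strand bias, the test
#' statistics of the biopsy-free cascade (Bonferroni-adjusted binomial p,
#' z statistic, adjusted z p-value and its log10, which stays finite below
#' double underflow), functional consequence, provenance (`M_FNA`, `M_P_FNA`,
#' `M_P_TR_BF`, `M_P_TR`) and filter tags (`PASS` or semicolon-separated
#' reasons).
#'
#' @return A zero-row data frame with the variant-call columns.
#' @export
empty_variant_calls <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), alt_reads = integer(), depth = integer(),
             maf = numeric(), strand_bias = numeric(),
             p_binomial_adj = numeric(), z_stat = numeric(),
             p_z_adj = numeric(), log10_p_z_adj = numeric(),
             consequence = character(), source = character(),
             filters = character(), stringsAsFactors = FALSE)
}

as_variant_calls <- function(df) {
  out <- empty_variant_calls()
  if (nrow(df) == 0) return(out)
  for (cc in VCALL_COLS) {
    if (!cc %in% names(df)) {
      df[[cc]] <- switch(cc,
        strand_bias = , p_binomial_adj = , z_stat = , p_z_adj = ,
        log10_p_z_adj = , maf = NA_real_,
        consequence = "unknown", source = NA_character_, filters = "PASS",
        NA)
    }
  }
  extra <- setdiff(names(df), VCALL_COLS)
  df[, c(VCALL_COLS, extra)]
}

#' Read or write a candidate variant table TSV
#'
#' The exchange format for tissue-caller outputs: tab-separated with columns
#' `chrom`, `pos`, `ref`, `alt`, `tumor_af`, `tumor_depth`, `germline_af`,
#' `germline_depth`, `caller` (mutect/varscan2/both) and `consequence`.
#'
#' @param path File path.
#' @param tab Data frame of tissue candidates.
#' @return `read_variant_table()` returns the validated data frame;
#'   `write_variant_table()` returns `path` invisibly.
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path)) stop("variant table not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "")
  need <- c("chrom", "pos", "ref", "alt", "tumor_af", "germline_af",
            "caller", "consequence")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("variant table: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"tumor_depth" %in% names(df)) df$tumor_depth <- NA_integer_
  if (!"germline_depth" %in% names(df)) df$germline_depth <- NA_integer_
  if (any(df$tumor_af < 0 | df$tumor_af > 1 |
          df$germline_af < 0 | df$germline_af > 1, na.rm = TRUE))
    stop("variant table: allele fractions must lie in [0, 1]", call. = FALSE)
  df
}

#' @rdname read_variant_table
#' @export
write_variant_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

fmt_info_num <- function(x, digits = 6) {
  ifelse(is.na(x), ".", formatC(x, digits = digits, format = "g"))
}

#' Write variant calls as VCF v4.2
#'
#' Site-only records (no genotype columns). INFO carries MAF, ALTREADS,
#' DEPTH, SB (strand bias), PBIN (Bonferroni-adjusted binomial p), PZ
#' (adjusted z-test p), CSQ (consequence) and SOURCE (provenance set). The
#' FILTER column carries `PASS` or the semicolon-separated filter tags.
#' Coordinates are 1-based throughout, matching the VCF convention.
#'
#' @param calls Variant-call data frame sorted by (chrom, pos).
#' @param sample_id Sample name recorded in the header.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, sample_id, path) {
  calls <- as_variant_calls(calls)
  if (nrow(calls) > 1) {
    ch <- as.integer(factor(calls$chrom, levels = unique(calls$chrom)))
    if (any(order(ch, calls$pos) != seq_len(nrow(calls))))
      stop("write_vcf: calls must be sorted by (chrom, pos)", call. = FALSE)
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=plasmatrack_%s",
            as.character(utils::packageVersion("plasmatrack"))),
    sprintf("##sample=%s", sample_id),
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Mutant allele fraction (alt reads / total Q30 depth)\">",
    "##INFO=<ID=ALTREADS,Number=1,Type=Integer,Description=\"Supporting reads for the alternative allele\">",
    "##INFO=<ID=DEPTH,Number=1,Type=Integer,Description=\"Total Q30 unique depth at the position\">",
    "##INFO=<ID=SB,Number=1,Type=Float,Description=\"Strand bias: majority-strand fraction of total depth\">",
    "##INFO=<ID=PBIN,Number=1,Type=Float,Description=\"Bonferroni-adjusted binomial p-value vs matched germline\">",
    "##INFO=<ID=PZ,Number=1,Type=Float,Description=\"Bonferroni-adjusted z-test p-value vs cross-plasma background\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Functional consequence\">",
    "##INFO=<ID=SOURCE,Number=1,Type=String,Description=\"Detection provenance: M_FNA, M_P_FNA, M_P_TR_BF or M_P_TR\">",
    "##FILTER=<ID=min_depth,Description=\"Total depth not over the minimum\">",
    "##FILTER=<ID=strand_bias,Description=\"Strand bias at or above the gate\">",
    "##FILTER=<ID=germline,Description=\"Allele present in matched germline above the germline maximum\">",
    "##FILTER=<ID=binom_p,Description=\"Binomial test vs germline not significant after Bonferroni\">",
    "##FILTER=<ID=no_background,Description=\"Too few background panel samples at the site\">",
    "##FILTER=<ID=z_p,Description=\"Adjusted z-test p-value above the significance gate\">",
    "##FILTER=<ID=min_alt_reads,Description=\"Fewer supporting reads than the minimum\">",
    "##FILTER=<ID=window_af,Description=\"Low-fraction candidate clustered with another candidate within the proximity window\">",
    "##FILTER=<ID=lane_snp,Description=\"Matches a germline SNP from a sample in the same flow-cell lane\">",
    "##FILTER=<ID=no_annotation,Description=\"No functional annotation available\">",
    "##FILTER=<ID=consequence,Description=\"Consequence class not reportable\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  recs <- character(0)
  if (nrow(calls) > 0) {
    info <- paste0(
      "MAF=", fmt_info_num(calls$maf),
      ";ALTREADS=", calls$alt_reads,
      ";DEPTH=", calls$depth,
      ";SB=", fmt_info_num(calls$strand_bias),
      ";PBIN=", fmt_info_num(calls$p_binomial_adj, digits = 4),
      ";PZ=", fmt_info_num(calls$p_z_adj, digits = 4),
      ";CSQ=", calls$consequence,
      ";SOURCE=", calls$source)
    filt <- ifelse(is.na(calls$filters) | calls$filters == "", "PASS",
                   calls$filters)
    recs <- paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".",
                  filt, info, sep = "\t")
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}
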