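#' Merge somatic candidates from two tissue callers
#'
#' Tissue-variant calling itself happens upstream (e.g. MuTect and Varscan2
#' against the matched germline); this merges their candidate tables into one
#' list, keeping variants identified by at least one caller. Records present
#' in both inputs collapse to a single record with `caller = "both"`; on
#' conflicting allele fractions the record with the higher tumor depth wins.
#'
#' @param a,b Tissue-candidate data frames (see [read_variant_table()]),
#'   each sorted by (chrom, pos).
#' @return Merged candidate data frame keyed by (chrom, pos, ref, alt).
#' @export
merge_caller_outputs <- function(a, b) {
  both <- rbind(a[, names(a)], b[, names(a)])
  if (nrow(both) == 0) return(a)
  pk <- paste(both$chrom, both$pos)
  refs <- tapply(both$ref, pk, function(r) length(unique(r)))
  if (any(refs > 1)) {
    bad <- names(refs)[refs > 1][1]
    stop("merge_caller_outputs: conflicting ref alleles at ", bad,
         call. = FALSE)
  }
  key <- paste(both$chrom, both$pos, both$ref, both$alt)
  in_a <- key %in% paste(a$chrom, a$pos, a$ref, a$alt)
  in_b <- key %in% paste(b$chrom, b$pos, b$ref, b$alt)
  dep <- ifelse(is.na(both$tumor_depth), -1, both$tumor_depth)
  ord <- order(key, -dep)
  both <- both[ord, ]
  keep <- !duplicated(key[ord])
  out <- both[keep, ]
  kk <- paste(out$chrom, out$pos, out$ref, out$alt)
  shared <- kk %in% key[in_a] & kk %in% key[in_b]
  out$caller[shared] <- "both"
  out <- out[order(out$chrom, out$pos, out$alt), ]
  rownames(out) <- NULL
  out
}

#' Apply the tissue-mutation frequency filters
#'
#' A merged candidate becomes a tissue mutation (the tumor-informed tracking
#' set) when its allele fraction in the matched germline is below 0.5%
#' (strict) and its tumor allele fraction reaches 4% (inclusive by default;
#' the boundary convention is configurable via `cfg$tumor_af_inclusive`).
#'
#' @param candidates Tissue-candidate data frame.
#' @param cfg A [run_config()].
#' @return List with `kept` (the tissue-mutation set, `source = "M_FNA"`) and
#'   `rejected` (the complement, with a `reason` column); together they
#'   partition the input.
#' @export
filter_mfna <- function(candidates, cfg = run_config()) {
  germ_ok <- candidates$germline_af < cfg$germline_max_af
  tumor_ok <- if (cfg$tumor_af_inclusive)
    candidates$tumor_af >= cfg$tumor_min_af else
      candidates$tumor_af > cfg$tumor_min_af
  reason <- rep(NA_character_, nrow(candidates))
  reason[!tumor_ok] <- "tumor_af"
  reason[!germ_ok] <- ifelse(is.na(reason[!germ_ok]), "germline_af",
                             paste(reason[!germ_ok], "germline_af",
                                   sep = ";"))
  kept <- candidates[is.na(reason), , drop = FALSE]
  if (nrow(kept) > 0) kept$source <- "M_FNA"
  rejected <- candidates[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  rownames(kept) <- rownames(rejected) <- NULL
  list(kept = kept, rejected = rejected)
}
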