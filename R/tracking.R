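#' Tumor-informed tracking of tissue mutations in plasma
#'
#' The tumor-informed test: for each tissue mutation, decides whether the
#' matched plasma sample carries it significantly above the technical
#' background. A variant is detected when all of the following hold:
#'
#' 1. its plasma allele fraction strictly exceeds the site's background
#'    95th percentile (from a panel that excludes this plasma sample);
#' 2. a one-sided binomial test of the supporting reads against the site's
#'    pooled background error rate (floored at `cfg$pooled_error_floor`)
#'    gives p below `cfg$track_p` (0.001);
#' 3. at least `cfg$track_min_alt_reads` supporting reads (3);
#' 4. strand bias strictly below `cfg$sb_max` (0.9);
#' 5. unique depth at least `cfg$track_min_depth` (200).
#'
#' The two statistical criteria are combined conjunctively and can be
#' switched individually in the configuration. At sites where fewer than
#' `cfg$bg_min_panel` panel samples contribute, the percentile rule is
#' unavailable and detection falls back to the binomial rule alone.
#' Positions absent from the plasma pileup are reported as `untestable`.
#'
#' @param variants Data frame of tissue mutations with columns `chrom`,
#'   `pos`, `ref`, `alt` (and optionally `consequence`).
#' @param plasma The matched plasma [pileup_table()].
#' @param bg A [build_background()] model built excluding `plasma`.
#' @param cfg A [run_config()].
#' @return A variant-call data frame with observed plasma statistics, a
#'   logical `detected` column, a `status` column (`tested`/`untestable`) and
#'   `source` set to `M_P_FNA` for detected calls.
#' @export
track_variants <- function(variants, plasma, bg, cfg = run_config()) {
  if (!is.null(attr(bg, "panel_samples")) &&
      pileup_sample_id(plasma) %in% attr(bg, "panel_samples"))
    stop("track_variants: background panel must exclude the plasma sample ",
         "under test", call. = FALSE)
  long <- pileup_long(plasma)
  li <- match(site_key(variants$chrom, variants$pos, variants$alt),
              site_key(long$chrom, long$pos, long$alt))
  bi <- match(site_key(variants$chrom, variants$pos, variants$alt),
              site_key(bg$chrom, bg$pos, bg$alt))
  n <- nrow(variants)
  alt_reads <- ifelse(is.na(li), NA_integer_, long$alt_reads[li])
  depth <- ifelse(is.na(li), NA_integer_, long$depth[li])
  af <- ifelse(is.na(li), NA_real_, long$af[li])
  sb <- ifelse(is.na(li), NA_real_, long$sb[li])
  q95 <- ifelse(is.na(bi), NA_real_, bg$q95_af[bi])
  bg_n <- ifelse(is.na(bi), 0L, bg$n[bi])
  pooled <- ifelse(is.na(bi), 0, bg$pooled_error[bi])
  p0 <- pmax(pooled, cfg$pooled_error_floor)
  p_bin <- ifelse(is.na(alt_reads) | is.na(depth), NA_real_,
                  stats::pbinom(alt_reads - 1L, depth, p0,
                                lower.tail = FALSE))
  pct_usable <- bg_n >= cfg$bg_min_panel & !is.na(q95)
  pass_pct <- !cfg$use_percentile_rule | !pct_usable | (af > q95)
  pass_bin <- !cfg$use_binomial_rule | (!is.na(p_bin) & p_bin < cfg$track_p)
  pass_reads <- !is.na(alt_reads) & alt_reads >= cfg$track_min_alt_reads
  pass_sb <- !is.na(sb) & sb < cfg$sb_max
  pass_depth <- !is.na(depth) & depth >= cfg$track_min_depth
  testable <- !is.na(li)
  detected <- testable & pass_pct & pass_bin & pass_reads & pass_sb &
    pass_depth
  out <- data.frame(
    chrom = variants$chrom, pos = variants$pos, ref = variants$ref,
    alt = variants$alt, alt_reads = alt_reads, depth = depth, maf = af,
    strand_bias = sb, p_binomial = p_bin, bg_q95 = q95, bg_n = bg_n,
    bg_pooled_error = pooled,
    consequence = if ("consequence" %in% names(variants))
      variants$consequence else "unknown",
    source = ifelse(detected, "M_P_FNA", "M_FNA"),
    detected = detected,
    status = ifelse(testable, "tested", "untestable"),
    stringsAsFactors = FALSE)
  out$filters <- ifelse(detected, "PASS", NA_character_)
  out
}

#' @rdname track_variants
#' @param v A single tissue mutation (one-row data frame or list with
#'   `chrom`, `pos`, `ref`, `alt`).
#' @export
track_variant <- function(v, plasma, bg, cfg = run_config()) {
  track_variants(as.data.frame(v, stringsAsFactors = FALSE), plasma, bg, cfg)
}

#' Cohort-level tracking sensitivity
#'
#' The fraction of tissue mutations recovered in the matched plasma samples,
#' reported as a percentage to one decimal place.
#'
#' @param x Either a variant-call data frame carrying a logical `detected`
#'   column (as returned by [track_variants()]) or the number of detected
#'   mutations.
#' @param total When `x` is a count, the total number of tissue mutations
#'   evaluated.
#' @return List with `n_total`, `n_detected` and `pct`.
#' @examples
#' tracking_sensitivity(28, 40)$pct  # 70.0
#' @export
tracking_sensitivity <- function(x, total = NULL) {
  if (is.data.frame(x)) {
    n_total <- nrow(x)
    n_detected <- sum(x$detected)
  } else {
    n_detected <- as.numeric(x)
    n_total <- as.numeric(total)
  }
  if (is.na(n_total) || n_total == 0)
    stop("tracking_sensitivity: undefined for zero tracked mutations",
         call. = FALSE)
  list(n_total = n_total, n_detected = n_detected,
       pct = round(100 * n_detected / n_total, 1))
}
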