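#' Prefilter testable sites of a plasma pileup
#'
#' A (position, alternative allele) pair enters the biopsy-free cascade only
#' when the position has total depth over 500 (`depth >= cfg$bf_min_depth`),
#' strand bias strictly under 0.9, and the allele has at least one
#' supporting read. Each of the three non-reference alleles at a position is
#' an independent hypothesis.
#'
#' @param plasma A [pileup_table()].
#' @param cfg A [run_config()].
#' @return The [pileup_long()] rows passing the prefilter.
#' @export
prefilter_sites <- function(plasma, cfg = run_config()) {
  long <- pileup_long(plasma)
  keep <- long$depth >= cfg$bf_min_depth &
    !is.na(long$sb) & long$sb < cfg$sb_max &
    long$alt_reads >= 1L
  out <- long[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exact binomial test of plasma abundance against matched germline
#'
#' One-sided upper-tail exact binomial test of whether a non-reference allele
#' is more abundant in plasma than in the matched germline: the null
#' probability is the germline allele fraction with a +0.5/+1 pseudocount,
#' `p0 = (germ_alt + 0.5) / (germ_depth + 1)`, so a germline with zero
#' supporting reads still yields a proper (non-degenerate) null. The test is
#' only meaningful where the germline fraction is below the germline maximum
#' (0.5%); the caller enforces that gate.
#'
#' @param alt,depth Supporting reads and total depth in plasma.
#' @param germ_alt,germ_depth Supporting reads and total depth in germline.
#' @return One-sided p-value `P(X >= alt | depth, p0)`; vectorized.
#' @examples
#' binomial_germline_test(0, 2000, 0, 2000)   # 1
#' binomial_germline_test(20, 2000, 1, 2000)  # far below 0.05
#' @export
binomial_germline_test <- function(alt, depth, germ_alt, germ_depth) {
  if (any(depth <= 0) || any(germ_depth < 0))
    stop("binomial_germline_test: depths must be positive", call. = FALSE)
  p0 <- (germ_alt + 0.5) / (germ_depth + 1)
  stats::pbinom(alt - 1L, depth, p0, lower.tail = FALSE)
}

#' z-test of a plasma allele fraction against the cross-plasma background
#'
#' Compares an observed allele fraction with the background distribution of
#' the same allele across other plasma samples:
#' `z = (af - mean_af) / max(sd_af, sd_floor)`, one-sided upper tail (somatic
#' signal is an excess over error). The standard-deviation floor,
#' `max(1 / panel mean depth, 1e-5)`, keeps sites whose panel shows zero
#' variance testable. The p-value is carried in log10 space so that the
#' extremely small values typical of true somatic signal (z of several
#' hundred) remain finite and comparable against the 1e-18 gate.
#'
#' @param af Observed allele fraction(s).
#' @param mean_af,sd_af Background mean and standard deviation at the site.
#' @param sd_floor Floor for the standard deviation.
#' @return List with `z`, `p` (0 below double underflow) and `log10_p`.
#' @export
ztest_background <- function(af, mean_af, sd_af, sd_floor = 1e-5) {
  z <- (af - mean_af) / pmax(sd_af, sd_floor)
  log10_p <- stats::pnorm(z, lower.tail = FALSE, log.p = TRUE) / log(10)
  list(z = z, p = 10^log10_p, log10_p = log10_p)
}

#' Biopsy-free somatic SNV calling in plasma
#'
#' The full biopsy-free cascade over a plasma pileup, producing final somatic
#' calls without any tissue information:
#'
#' 1. [prefilter_sites()]: depth over 500, strand bias under 0.9, at least
#'    one supporting read;
#' 2. germline gate: the matched germline must carry the allele below 0.5%;
#' 3. [binomial_germline_test()], Bonferroni-corrected over the hypotheses
#'    tested in this sample; keep adjusted p below `cfg$binomial_alpha`;
#' 4. [ztest_background()] against the cross-plasma background,
#'    Bonferroni-corrected (in log10 space, without clamping); keep adjusted
#'    p at or below `cfg$z_p_max` (1e-18);
#' 5. discard candidates with fewer than 8 supporting reads;
#' 6. proximity window: when two or more surviving candidates lie within 10
#'    bp, those with allele fraction below 20% are discarded;
#' 7. lane-SNP filter: candidates matching a germline SNP seen in another
#'    sample from the same flow-cell lane are discarded (multiplexing
#'    cross-contamination);
#' 8. consequence filter: only nonsynonymous, stop-gain, stop-loss and
#'    splicing-disrupting variants are reported.
#'
#' Every candidate entering the cascade leaves it exactly once: either as a
#' final call or in the drop log with the reason of the first filter it
#' failed.
#'
#' @param plasma,germline Matched plasma and germline [pileup_table()]s.
#' @param bg A [build_background()] model built from *other* plasma samples.
#' @param annotations Functional annotations: data frame with `chrom`, `pos`,
#'   `ref`, `alt`, `consequence`. Candidates missing from the table are
#'   dropped with reason `no_annotation`. `NULL` labels every candidate
#'   nonsynonymous — intended for technical assays (e.g. replicate
#'   false-positive runs) where consequence is irrelevant and must not mask
#'   the error behaviour under study.
#' @param lane_snps Character vector of `chrom:pos:alt` keys of germline SNPs
#'   observed in same-lane samples.
#' @param cfg A [run_config()].
#' @return List with `calls` (final variant-call data frame, source
#'   `M_P_TR_BF`) and `dropped` (candidates with a `reason` column).
#' @export
call_biopsy_free <- function(plasma, germline, bg, annotations = NULL,
                             lane_snps = character(0), cfg = run_config()) {
  if (is.null(germline))
    stop("call_biopsy_free: matched germline pileup is required",
         call. = FALSE)
  if (!is.null(attr(bg, "panel_samples")) &&
      pileup_sample_id(plasma) %in% attr(bg, "panel_samples"))
    stop("call_biopsy_free: background panel must exclude the plasma sample ",
         "under test", call. = FALSE)
  long <- pileup_long(plasma)
  cand <- long[long$alt_reads >= 1L, , drop = FALSE]
  rownames(cand) <- NULL
  nc <- nrow(cand)
  reason <- rep(NA_character_, nc)
  p_b_adj <- z_stat <- p_z_adj <- log10_p_z_adj <- rep(NA_real_, nc)
  csq <- rep(NA_character_, nc)

  reason[cand$depth < cfg$bf_min_depth] <- "min_depth"
  sb_bad <- is.na(reason) & (is.na(cand$sb) | cand$sb >= cfg$sb_max)
  reason[sb_bad] <- "strand_bias"

  gl <- pileup_long(germline)
  gi <- match(site_key(cand$chrom, cand$pos, cand$alt),
              site_key(gl$chrom, gl$pos, gl$alt))
  g_alt <- ifelse(is.na(gi), 0L, gl$alt_reads[gi])
  g_dep <- ifelse(is.na(gi), 0L, gl$depth[gi])
  g_af <- ifelse(g_dep > 0, g_alt / g_dep, 0)
  reason[is.na(reason) & g_af >= cfg$germline_max_af] <- "germline"

  alive <- is.na(reason)
  m_b <- sum(alive)
  if (m_b > 0) {
    p_b <- binomial_germline_test(cand$alt_reads[alive], cand$depth[alive],
                                  g_alt[alive], g_dep[alive])
    p_b_adj[alive] <- pmin(1, p_b * m_b)
    fail <- alive
    fail[alive] <- !(p_b_adj[alive] < cfg$binomial_alpha)
    reason[fail] <- "binom_p"
  }

  alive <- is.na(reason)
  bi <- match(site_key(cand$chrom, cand$pos, cand$alt),
              site_key(bg$chrom, bg$pos, bg$alt))
  testable <- !is.na(bi) & bg$n[bi] >= cfg$bg_min_panel
  reason[alive & !testable] <- "no_background"
  alive <- is.na(reason)
  m_z <- sum(alive)
  if (m_z > 0) {
    sd_floor <- max(1 / attr(bg, "panel_mean_depth"), 1e-5)
    zt <- ztest_background(cand$af[alive], bg$mean_af[bi[alive]],
                           bg$sd_af[bi[alive]], sd_floor = sd_floor)
    z_stat[alive] <- zt$z
    log10_p_z_adj[alive] <- zt$log10_p + log10(m_z)
    p_z_adj[alive] <- pmin(1, 10^log10_p_z_adj[alive])
    fail <- alive
    fail[alive] <- !(log10_p_z_adj[alive] <= log10(cfg$z_p_max))
    reason[fail] <- "z_p"
  }

  alive <- is.na(reason)
  reason[alive & cand$alt_reads < cfg$bf_min_alt_reads] <- "min_alt_reads"

  # proximity-window rule, applied once to the surviving set
  alive <- which(is.na(reason))
  if (length(alive) >= 2) {
    ord <- alive[order(cand$chrom[alive], cand$pos[alive])]
    pos <- cand$pos[ord]
    chrom <- cand$chrom[ord]
    nn <- length(ord)
    gap_prev <- c(Inf, ifelse(chrom[-1] == chrom[-nn], diff(pos), Inf))
    gap_next <- c(gap_prev[-1], Inf)
    clustered <- pmin(gap_prev, gap_next) <= cfg$window_bp
    low <- clustered & cand$af[ord] < cfg$window_af
    reason[ord[low]] <- "window_af"
  }

  alive <- is.na(reason)
  if (length(lane_snps) > 0) {
    hit <- site_key(cand$chrom, cand$pos, cand$alt) %in% lane_snps
    reason[alive & hit] <- "lane_snp"
  }

  alive <- is.na(reason)
  if (is.null(annotations)) {
    csq[alive] <- "nonsynonymous"
  } else {
    ai <- match(site_key(cand$chrom, cand$pos, cand$alt),
                site_key(annotations$chrom, annotations$pos,
                         annotations$alt))
    csq <- ifelse(is.na(ai), NA_character_, annotations$consequence[ai])
    reason[alive & is.na(csq)] <- "no_annotation"
    alive <- is.na(reason)
    reason[alive & !csq %in% DELETERIOUS] <- "consequence"
  }

  alive <- is.na(reason)
  calls <- if (!any(alive)) empty_variant_calls() else data.frame(
    chrom = cand$chrom[alive], pos = cand$pos[alive], ref = cand$ref[alive],
    alt = cand$alt[alive], alt_reads = cand$alt_reads[alive],
    depth = cand$depth[alive], maf = cand$af[alive],
    strand_bias = cand$sb[alive], p_binomial_adj = p_b_adj[alive],
    z_stat = z_stat[alive], p_z_adj = p_z_adj[alive],
    log10_p_z_adj = log10_p_z_adj[alive],
    consequence = csq[alive], source = "M_P_TR_BF", filters = "PASS",
    stringsAsFactors = FALSE)
  dropped <- cand[!is.na(reason), , drop = FALSE]
  dropped$reason <- reason[!is.na(reason)]
  dropped$p_binomial_adj <- p_b_adj[!is.na(reason)]
  dropped$z_stat <- z_stat[!is.na(reason)]
  dropped$log10_p_z_adj <- log10_p_z_adj[!is.na(reason)]
  rownames(calls) <- rownames(dropped) <- NULL
  list(calls = calls, dropped = dropped)
}

#' Replicate-pair false-positive assay
#'
#' Runs the biopsy-free caller over technical replicate pairs, treating one
#' member of each pair as a mock plasma sample and the other as its matched
#' germline. Because both members are draws from the same DNA, every call is
#' a false positive by construction; the assay measures the caller's
#' false-discovery behaviour on pure technical background. Consequence
#' annotation is bypassed (every candidate treated as reportable) so the
#' count reflects the statistical filters alone.
#'
#' @param pairs List of replicate pairs from [simulate_replicate_pairs()]
#'   (each element a list with `a` and `b`).
#' @param bg A [build_background()] model from an independent plasma panel
#'   sharing the assay's error structure.
#' @param cfg A [run_config()].
#' @return Total number of calls across all pairs (integer), with the
#'   per-pair counts as an attribute.
#' @export
false_positive_assay <- function(pairs, bg, cfg = run_config()) {
  per_pair <- vapply(pairs, function(pr) {
    nrow(call_biopsy_free(pr$a, pr$b, bg, annotations = NULL,
                          lane_snps = character(0), cfg = cfg)$calls)
  }, integer(1))
  structure(sum(per_pair), per_pair = per_pair)
}
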