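#' Merge tracked and biopsy-free plasma calls
#'
#' Combines the tumor-informed detections (tissue mutations recovered in
#' plasma) with the biopsy-free calls from the same plasma sample into the
#' unified target-region mutation set used for burden monitoring. The union
#' is keyed by (chrom, pos, ref, alt); on overlap the biopsy-free record wins
#' (it carries the richer statistics) and a single record is kept. All output
#' records carry `source = "M_P_TR"`.
#'
#' @param tracked Variant calls from [track_variants()]; only rows with
#'   `detected = TRUE` enter the union (when a `detected` column is present).
#' @param bf Final calls from [call_biopsy_free()].
#' @return A variant-call data frame sorted by (chrom, pos, alt).
#' @export
merge_mptr <- function(tracked, bf) {
  if (!is.null(tracked) && "detected" %in% names(tracked))
    tracked <- tracked[tracked$detected, , drop = FALSE]
  tr <- as_variant_calls(if (is.null(tracked)) empty_variant_calls() else
    tracked)[, VCALL_COLS]
  bfc <- as_variant_calls(if (is.null(bf)) empty_variant_calls() else
    bf)[, VCALL_COLS]
  both <- rbind(bfc, tr)  # bf first so it wins on duplicates
  key <- paste(both$chrom, both$pos, both$ref, both$alt)
  out <- both[!duplicated(key), , drop = FALSE]
  out$source <- rep("M_P_TR", nrow(out))
  out <- out[order(out$chrom, out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detection rate with exact binomial confidence interval
#'
#' Point estimate as a percentage to one decimal place, with the exact
#' two-sided Clopper-Pearson 95% confidence interval (the interval obtained
#' by inverting binomial tail probabilities).
#'
#' @param detected Number of positive samples.
#' @param total Number of samples tested (> 0).
#' @param conf_level Confidence level, default 0.95.
#' @return List with `n_detected`, `n_total`, `pct` (1 decimal), `ci_low`,
#'   `ci_high` (percent, full precision).
#' @examples
#' detection_rate(15, 17)$pct  # 88.2
#' detection_rate(22, 23)      # CI approximately 78.05 to 99.89
#' @export
detection_rate <- function(detected, total, conf_level = 0.95) {
  if (length(total) != 1 || is.na(total) || total <= 0)
    stop("detection_rate: total must be positive", call. = FALSE)
  if (detected < 0 || detected > total)
    stop("detection_rate: detected must lie in [0, total]", call. = FALSE)
  ci <- stats::binom.test(detected, total, conf.level = conf_level)$conf.int
  list(n_detected = detected, n_total = total,
       pct = round(100 * detected / total, 1),
       ci_low = 100 * ci[1], ci_high = 100 * ci[2])
}

#' One-way ANOVA with Fisher's LSD post-hoc tests
#'
#' Tests whether group means differ (one-way ANOVA) and, for each pair of
#' groups, a two-tailed t-test using the pooled within-group mean square with
#' the ANOVA residual degrees of freedom (Fisher's least significant
#' difference procedure, unadjusted for multiplicity as is conventional for
#' LSD).
#'
#' Groups with fewer than two observations are excluded with a warning; at
#' least two usable groups are required.
#'
#' @param groups Named list of numeric vectors, one per group.
#' @return List with `F`, `p`, `df_between`, `df_within`, `ms_within`,
#'   `group_means`, and `pairwise` (data frame: `g1`, `g2`, `diff`, `t`,
#'   `p`).
#' @export
anova_lsd <- function(groups) {
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("anova_lsd: groups must be named", call. = FALSE)
  sizes <- lengths(groups)
  small <- names(groups)[sizes < 2]
  if (length(small) > 0) {
    groups <- groups[sizes >= 2]
    if (length(groups) >= 2)
      warning("anova_lsd: excluding group(s) with fewer than 2 observations: ",
              paste(small, collapse = ", "), call. = FALSE)
  }
  if (length(groups) < 2)
    stop("anova_lsd: need at least two groups with >= 2 observations each",
         call. = FALSE)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  fit <- stats::aov(y ~ g)
  tab <- summary(fit)[[1]]
  ms_within <- tab$`Mean Sq`[2]
  df_within <- tab$Df[2]
  means <- vapply(groups, mean, numeric(1))
  ns <- lengths(groups)
  cmb <- utils::combn(names(groups), 2)
  pw <- data.frame(g1 = cmb[1, ], g2 = cmb[2, ], stringsAsFactors = FALSE)
  pw$diff <- means[pw$g1] - means[pw$g2]
  se <- sqrt(ms_within * (1 / ns[pw$g1] + 1 / ns[pw$g2]))
  pw$t <- as.numeric(pw$diff / se)
  pw$p <- 2 * stats::pt(-abs(pw$t), df_within)
  rownames(pw) <- NULL
  list(F = tab$`F value`[1], p = tab$`Pr(>F)`[1],
       df_between = tab$Df[1], df_within = df_within,
       ms_within = ms_within, group_means = means, pairwise = pw)
}

#' Per-sample tumor-burden records
#'
#' Reduces each plasma sample's merged mutation set to the burden quantities
#' tracked longitudinally: the number of mutations detected and their mean
#' and maximum allele fraction. Samples with no detected mutations carry
#' `n_variants = 0` and undefined (NA) allele-fraction summaries, and are
#' excluded from allele-fraction group averages downstream (plotted as
#' not-detected in the source study).
#'
#' @param calls_by_sample Named list of merged call data frames
#'   (see [merge_mptr()]), keyed by plasma sample id.
#' @param sheet A [sample_sheet()]; a `disease_status` column
#'   (Dx/CR_PR/SD/PD/NA) is carried through when present.
#' @return Data frame with one row per plasma sample: `sample_id`,
#'   `patient_id`, `timepoint_days`, `disease_status`, `n_variants`,
#'   `mean_maf`, `max_maf`.
#' @export
burden_records <- function(calls_by_sample, sheet) {
  ids <- names(calls_by_sample)
  si <- match(ids, sheet$sample_id)
  if (anyNA(si))
    stop("burden_records: sample(s) missing from sheet: ",
         paste(ids[is.na(si)], collapse = ", "), call. = FALSE)
  n_var <- vapply(calls_by_sample, nrow, integer(1))
  mean_maf <- vapply(calls_by_sample, function(d)
    if (nrow(d) > 0) mean(d$maf) else NA_real_, numeric(1))
  max_maf <- vapply(calls_by_sample, function(d)
    if (nrow(d) > 0) max(d$maf) else NA_real_, numeric(1))
  data.frame(
    sample_id = ids, patient_id = sheet$patient_id[si],
    timepoint_days = sheet$timepoint_days[si],
    disease_status = if ("disease_status" %in% names(sheet))
      sheet$disease_status[si] else NA_character_,
    n_variants = n_var, mean_maf = mean_maf, max_maf = max_maf,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Group burden statistics by disease status
#'
#' Splits burden records by disease status and reports per-group mean, median
#' and standard error for the mean allele fraction (detected samples only)
#' and the number of variants (all samples), together with one-way ANOVA and
#' LSD post-hoc tests on both quantities.
#'
#' @param records A [burden_records()] data frame with `disease_status`
#'   populated.
#' @param pd_dates Optional named vector of progressive-disease dates per
#'   patient (same time scale as `timepoint_days`); when given, records are
#'   first relabelled with [reassign_pd_window()].
#' @param window_days Window for the PD reassignment, default 90.
#' @return List with `group_stats` (data frame), `anova_mean_maf` and
#'   `anova_n_variants` (each an [anova_lsd()] result, or NULL when fewer
#'   than two usable groups exist for that quantity).
#' @export
burden_summaries <- function(records, pd_dates = NULL, window_days = 90) {
  if (!is.null(pd_dates))
    records <- reassign_pd_window(records, pd_dates, window_days)
  records <- records[!is.na(records$disease_status), , drop = FALSE]
  if (nrow(records) == 0 || length(unique(records$disease_status)) < 2)
    stop("burden_summaries: need at least two non-empty disease-status groups",
         call. = FALSE)
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  gs <- do.call(rbind, lapply(split(records, records$disease_status),
    function(d) {
      maf <- d$mean_maf[!is.na(d$mean_maf)]
      data.frame(
        disease_status = d$disease_status[1], n_samples = nrow(d),
        n_detected = sum(d$n_variants > 0),
        mean_maf = if (length(maf)) mean(maf) else NA_real_,
        median_maf = if (length(maf)) stats::median(maf) else NA_real_,
        sem_maf = if (length(maf) > 1) sem(maf) else NA_real_,
        mean_n_variants = mean(d$n_variants),
        median_n_variants = stats::median(d$n_variants),
        sem_n_variants = if (nrow(d) > 1) sem(d$n_variants) else NA_real_,
        stringsAsFactors = FALSE)
    }))
  rownames(gs) <- NULL
  maf_groups <- lapply(split(records$mean_maf, records$disease_status),
                       function(x) x[!is.na(x)])
  nv_groups <- split(as.numeric(records$n_variants), records$disease_status)
  try_lsd <- function(g) tryCatch(suppressWarnings(anova_lsd(g)),
                                  error = function(e) NULL)
  list(group_stats = gs,
       anova_mean_maf = try_lsd(maf_groups),
       anova_n_variants = try_lsd(nv_groups))
}

#' Move records shortly preceding progression into the PD group
#'
#' Rising ctDNA tends to precede the radiological call of progressive
#' disease; to account for the lag, any record obtained less than
#' `window_days` (default 90, i.e. 3 months) before a patient's PD date is
#' relabelled PD regardless of its original group.
#'
#' @param records A [burden_records()] data frame.
#' @param pd_dates Named numeric vector: PD date per patient, on the
#'   `timepoint_days` scale. Patients without an entry are untouched.
#' @param window_days Width of the pre-PD window.
#' @return The records with `disease_status` relabelled where
#'   `0 < pd_date - timepoint_days < window_days`.
#' @export
reassign_pd_window <- function(records, pd_dates, window_days = 90) {
  pd <- pd_dates[records$patient_id]
  lag <- pd - records$timepoint_days
  hit <- !is.na(lag) & lag > 0 & lag < window_days
  records$disease_status[hit] <- "PD"
  records
}

#' Sensitivity and specificity against a reference assay
#'
#' Paired per-sample detection calls from the sequencing method and a
#' reference method (e.g. droplet digital PCR) reduced to sensitivity
#' (TP / (TP + FN)) and specificity (TN / (TN + FP)), each with an exact
#' Clopper-Pearson 95% confidence interval. When the reference contains no
#' positives (or no negatives) the corresponding metric is undefined and
#' returned as NULL.
#'
#' @param seq_calls,ref_calls Equal-length logical vectors.
#' @return List with `tp`, `fp`, `tn`, `fn`, `sensitivity`, `specificity`
#'   (each a [detection_rate()] result or NULL).
#' @export
concordance <- function(seq_calls, ref_calls) {
  if (length(seq_calls) != length(ref_calls))
    stop("concordance: vectors must have equal length", call. = FALSE)
  seq_calls <- as.logical(seq_calls)
  ref_calls <- as.logical(ref_calls)
  tp <- sum(seq_calls & ref_calls)
  fp <- sum(seq_calls & !ref_calls)
  tn <- sum(!seq_calls & !ref_calls)
  fn <- sum(!seq_calls & ref_calls)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = if (tp + fn > 0) detection_rate(tp, tp + fn) else NULL,
       specificity = if (tn + fp > 0) detection_rate(tn, tn + fp) else NULL)
}

#' Theoretical limit of detection from unique depth
#'
#' With a fixed minimum of supporting reads (default 8), the lowest allele
#' fraction the biopsy-free caller can report at a site is
#' `min_alt_reads / unique_depth`: the caller uses no explicit allele-
#' fraction threshold, so depth alone sets the floor.
#'
#' @param unique_depth Unique (deduplicated) depth at the site; positive.
#' @param min_alt_reads Supporting-read threshold, default 8.
#' @return The lowest detectable allele fraction; vectorized over depth.
#' @examples
#' theoretical_lod(800)   # 0.01
#' theoretical_lod(5532)  # ~0.00145
#' @export
theoretical_lod <- function(unique_depth, min_alt_reads = 8) {
  if (any(unique_depth <= 0))
    stop("theoretical_lod: unique_depth must be positive", call. = FALSE)
  if (min_alt_reads < 0)
    stop("theoretical_lod: min_alt_reads must be non-negative", call. = FALSE)
  min_alt_reads / unique_depth
}

#' Haploid genome equivalents of an input DNA mass
#'
#' Input DNA mass caps the number of distinct template molecules and hence
#' the attainable unique depth: one haploid human genome weighs about
#' 3.3 pg, so `input_ng / 0.0033` is the maximum number of genome
#' equivalents (and the effective ceiling on unique coverage).
#'
#' @param input_ng Input DNA mass in nanograms; positive.
#' @return Number of haploid genome copies; vectorized.
#' @examples
#' genome_equivalents(50)   # ~15152
#' genome_equivalents(7.8)  # ~2364
#' @export
genome_equivalents <- function(input_ng) {
  if (any(input_ng <= 0))
    stop("genome_equivalents: input mass must be positive", call. = FALSE)
  input_ng / 0.0033
}

#' Limit of detection under the input-mass cap
#'
#' The effective unique depth cannot exceed the number of input genome
#' equivalents; the attainable limit of detection is therefore evaluated at
#' `min(raw_depth, genome_equivalents(input_ng))`.
#'
#' @param raw_depth Sequenced unique depth.
#' @param input_ng Input DNA mass in ng.
#' @param min_alt_reads Supporting-read threshold, default 8.
#' @return List with `effective_depth` and `lod`.
#' @export
lod_with_input_cap <- function(raw_depth, input_ng, min_alt_reads = 8) {
  eff <- pmin(raw_depth, genome_equivalents(input_ng))
  list(effective_depth = eff,
       lod = theoretical_lod(eff, min_alt_reads))
}
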