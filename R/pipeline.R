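#' Derive tissue-caller candidates from a simulated cohort
#'
#' Stand-in for the upstream tissue callers when running on synthetic data:
#' for each ground-truth variant of a patient, reads the observed allele
#' fraction and depth out of the FNA and PBL pileups and emits a
#' tissue-candidate record (caller `both`). Only the measurement is
#' simulated; the downstream frequency filters are the real ones.
#'
#' @param truth Truth table from [simulate_cohort()] for one patient.
#' @param fna,pbl The patient's FNA and PBL [pileup_table()]s.
#' @return A tissue-candidate data frame (see [read_variant_table()]).
#' @export
derive_tissue_candidates <- function(truth, fna, pbl) {
  fl <- pileup_long(fna)
  gl <- pileup_long(pbl)
  key <- site_key(truth$chrom, truth$pos, truth$alt)
  fi <- match(key, site_key(fl$chrom, fl$pos, fl$alt))
  gi <- match(key, site_key(gl$chrom, gl$pos, gl$alt))
  data.frame(
    chrom = truth$chrom, pos = truth$pos, ref = truth$ref, alt = truth$alt,
    tumor_af = fl$af[fi], tumor_depth = fl$depth[fi],
    germline_af = gl$af[gi], germline_depth = gl$depth[gi],
    caller = "both", consequence = truth$consequence,
    stringsAsFactors = FALSE)
}

#' Collect germline SNP keys per flow-cell lane
#'
#' For the multiplexing cross-contamination filter: a site counts as a
#' germline SNP of a lane when any germline (PBL) sample sequenced in that
#' lane carries a non-reference allele at or above `cfg$lane_snp_min_af`
#' (default 25%).
#'
#' @param germline_pileups Named list of PBL [pileup_table()]s.
#' @param sheet A [sample_sheet()] assigning samples to lanes.
#' @param cfg A [run_config()].
#' @return Named list: for each lane, a character vector of `chrom:pos:alt`
#'   keys paired with the contributing sample ids as names.
#' @export
find_lane_snps <- function(germline_pileups, sheet, cfg = run_config()) {
  lanes <- list()
  for (s in names(germline_pileups)) {
    lane <- sheet$lane_batch[match(s, sheet$sample_id)]
    if (is.na(lane)) next
    gl <- pileup_long(germline_pileups[[s]])
    hit <- gl$af >= cfg$lane_snp_min_af & gl$alt_reads > 0
    if (!any(hit)) next
    keys <- stats::setNames(site_key(gl$chrom[hit], gl$pos[hit], gl$alt[hit]),
                            rep(s, sum(hit)))
    lanes[[lane]] <- c(lanes[[lane]], keys)
  }
  lanes
}

lane_snps_for_sample <- function(lanes, sheet, sample_id) {
  rec <- sheet[sheet$sample_id == sample_id, , drop = FALSE]
  if (nrow(rec) == 0) return(character(0))
  keys <- lanes[[rec$lane_batch]]
  if (is.null(keys)) return(character(0))
  # only SNPs observed in *other* patients' samples count
  own <- sheet$sample_id[sheet$patient_id == rec$patient_id]
  unname(unique(keys[!names(keys) %in% own]))
}

#' Run the full detection and monitoring pipeline on a simulated cohort
#'
#' End-to-end orchestration: simulate a matched cohort, build a leave-one-out
#' cross-plasma background per plasma sample, derive and filter tissue
#' mutations, track them in the matched plasma, call biopsy-free somatic
#' SNVs, merge the two call sets, summarize tumor burden, and write all
#' artifacts (per-sample VCFs and drop logs, background model, tracking
#' summary, burden table, statistics JSON, run manifest with config hash and
#' seed). Identical configuration and seed reproduce every artifact byte for
#' byte.
#'
#' @param out_dir Output directory (created if missing).
#' @param sim_cfg A [simulation_config()] describing the cohort.
#' @param cfg A [run_config()].
#' @param seed Seed overriding `sim_cfg$seed` when given.
#' @param write_pileups Also write the simulated pileup TSVs (off by default;
#'   they dominate output size).
#' @return Invisibly, a list with `manifest` (file table with checksums),
#'   `burden`, `summaries`, `calls` (per-sample merged call sets) and
#'   `tracking` (per-sample tracking tables).
#' @export
run_end_to_end <- function(out_dir, sim_cfg = simulation_config(),
                           cfg = run_config(), seed = NULL,
                           write_pileups = FALSE) {
  if (!is.null(seed)) sim_cfg$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  co <- simulate_cohort(sim_cfg)
  sheet <- co$sheet
  plasma_ids <- sheet$sample_id[sheet$material == "PLASMA"]
  pbl_of <- function(pat) sheet$sample_id[sheet$patient_id == pat &
                                            sheet$material == "PBL"][1]
  fna_of <- function(pat) sheet$sample_id[sheet$patient_id == pat &
                                            sheet$material == "FNA"][1]
  plasma <- co$pileups[plasma_ids]
  tumor_paired <- stats::setNames(lapply(plasma_ids, function(s)
    co$pileups[[fna_of(sheet$patient_id[sheet$sample_id == s])]]), plasma_ids)
  germ_paired <- stats::setNames(lapply(plasma_ids, function(s)
    co$pileups[[pbl_of(sheet$patient_id[sheet$sample_id == s])]]), plasma_ids)
  germline_pileups <- co$pileups[sheet$sample_id[sheet$material == "PBL"]]
  lanes <- find_lane_snps(germline_pileups, sheet, cfg)
  annotations <- co$truth[, c("chrom", "pos", "ref", "alt", "consequence")]

  write_sample_sheet(sheet, file.path(out_dir, "sample_sheet.tsv"))
  if (write_pileups) {
    pdir <- file.path(out_dir, "pileups")
    dir.create(pdir, showWarnings = FALSE)
    for (s in names(co$pileups))
      write_pileup(co$pileups[[s]], file.path(pdir, paste0(s, ".tsv")))
  }
  bg_all <- build_background(plasma, tumor = tumor_paired,
                             germline = germ_paired, cfg = cfg)
  write_background(bg_all, file.path(out_dir, "background_panel.tsv"))

  tracking <- list()
  calls <- list()
  drop_rows <- list()
  for (s in plasma_ids) {
    pat <- sheet$patient_id[sheet$sample_id == s]
    bg <- build_background(plasma, tumor = tumor_paired,
                           germline = germ_paired, cfg = cfg,
                           exclude_sample = s)
    tv <- co$truth[co$truth$patient_id == pat & co$truth$in_fna, ,
                   drop = FALSE]
    mfna <- if (nrow(tv) > 0) {
      cand <- derive_tissue_candidates(tv, co$pileups[[fna_of(pat)]],
                                       co$pileups[[pbl_of(pat)]])
      filter_mfna(cand, cfg)$kept
    } else NULL
    tr <- if (!is.null(mfna) && nrow(mfna) > 0)
      track_variants(mfna, co$pileups[[s]], bg, cfg) else NULL
    bf <- call_biopsy_free(co$pileups[[s]], germ_paired[[s]], bg,
                           annotations = annotations,
                           lane_snps = lane_snps_for_sample(lanes, sheet, s),
                           cfg = cfg)
    merged <- merge_mptr(tr, bf$calls)
    tracking[[s]] <- tr
    calls[[s]] <- merged
    write_vcf(merged, s, file.path(out_dir, paste0(s, ".vcf")))
    dl <- bf$dropped
    dl$sample_id <- rep(s, nrow(dl))
    drop_rows[[s]] <- dl
  }
  drop_log <- do.call(rbind, drop_rows)
  utils::write.table(drop_log, file.path(out_dir, "drop_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  tr_summary <- do.call(rbind, lapply(plasma_ids, function(s) {
    tr <- tracking[[s]]
    data.frame(sample_id = s,
               patient_id = sheet$patient_id[sheet$sample_id == s],
               timepoint_days = sheet$timepoint_days[sheet$sample_id == s],
               n_tracked = if (is.null(tr)) 0L else nrow(tr),
               n_detected = if (is.null(tr)) 0L else sum(tr$detected),
               mean_detected_maf = if (!is.null(tr) && any(tr$detected))
                 mean(tr$maf[tr$detected]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(tr_summary, file.path(out_dir, "tracking_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  burden <- burden_records(calls, sheet)
  utils::write.table(burden, file.path(out_dir, "burden.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summaries <- tryCatch(burden_summaries(burden), error = function(e) NULL)

  stats_out <- list(
    n_patients = sim_cfg$n_patients,
    n_plasma_samples = length(plasma_ids),
    n_mfna = sum(vapply(tracking, function(t)
      if (is.null(t)) 0L else nrow(t), integer(1))),
    tracking = if (sum(tr_summary$n_tracked) > 0)
      tracking_sensitivity(sum(tr_summary$n_detected),
                           sum(tr_summary$n_tracked)) else NULL,
    detection = detection_rate(sum(burden$n_variants > 0), nrow(burden)),
    anova_mean_maf = if (!is.null(summaries) &&
                         !is.null(summaries$anova_mean_maf))
      summaries$anova_mean_maf[c("F", "p")] else NULL,
    anova_n_variants = if (!is.null(summaries) &&
                           !is.null(summaries$anova_n_variants))
      summaries$anova_n_variants[c("F", "p")] else NULL)
  jsonlite::write_json(stats_out, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  cfg_path <- file.path(out_dir, "run_config.yaml")
  write_run_config(cfg, cfg_path)
  files <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.json")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    stringsAsFactors = FALSE)
  jsonlite::write_json(
    list(seed = sim_cfg$seed,
         config_md5 = unname(tools::md5sum(cfg_path)),
         files = manifest),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, burden = burden, summaries = summaries,
                 calls = calls, tracking = tracking))
}
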