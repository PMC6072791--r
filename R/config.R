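#' Analysis thresholds for ctDNA detection
#'
#' Bundles every tunable threshold of the detection pipeline with its default.
#' Defaults mirror the published protocol: non-reference alleles are tested in
#' plasma only where the matched germline carries them below 0.5%, tissue
#' mutations require a tumor allele fraction of at least 4%, biopsy-free
#' candidates need total depth over 500, strand bias under 0.9, at least 8
#' supporting reads, a Bonferroni-adjusted z-test p-value no larger than
#' 1e-18, and are pruned when two candidates fall inside a 10 bp window with
#' allele fraction below 20%. Tumor-informed tracking uses the 95th
#' percentile of the cross-plasma background distribution together with a
#' binomial test at p < 0.001.
#'
#' @param germline_max_af Maximum germline (PBL) allele fraction for a site to
#'   be considered somatic-testable (strict `<`). Default 0.005.
#' @param tumor_min_af Minimum tumor allele fraction for a tissue mutation.
#'   Default 0.04.
#' @param tumor_af_inclusive Whether the tumor AF boundary is inclusive
#'   (`>= tumor_min_af`, default) or strict.
#' @param sb_max Strand-bias gate: positions pass iff strand bias is strictly
#'   below this value. Default 0.9.
#' @param bf_min_depth Minimum total depth for biopsy-free testing; depth must
#'   be `>= bf_min_depth`, i.e. the default 501 encodes "over 500".
#' @param bf_min_alt_reads Minimum supporting reads for a biopsy-free call.
#'   Default 8.
#' @param window_bp,window_af Proximity filter: when two or more surviving
#'   candidates fall within `window_bp` base pairs, those with allele fraction
#'   below `window_af` are discarded. Defaults 10 bp and 0.20.
#' @param z_p_max Bonferroni-adjusted z-test significance gate (evaluated in
#'   log10 space, so values far below double underflow are handled). Default
#'   1e-18.
#' @param binomial_alpha Post-Bonferroni significance level for the binomial
#'   plasma-vs-germline test. Default 0.05.
#' @param track_percentile Background percentile a tracked variant must exceed.
#'   Default 95.
#' @param track_p Binomial p-value gate for tracked variants. Default 0.001.
#' @param track_min_alt_reads,track_min_depth Minimum supporting reads (3) and
#'   unique depth (200) for the tracking test.
#' @param bg_tumor_max_af,bg_germline_max_af,bg_min_depth_tumor,bg_min_depth_pbl,bg_min_depth_plasma
#'   Background-panel inclusion filters: a panel plasma sample contributes its
#'   allele fraction at a site only when the paired tumor AF is < 2.5% at
#'   tumor depth >= 250, the paired germline AF is < 0.5% at PBL depth >= 500,
#'   and its own plasma depth is >= 500.
#' @param bg_min_panel Minimum number of contributing panel samples for a site
#'   to be z-testable. Default 5.
#' @param lane_snp_min_af Allele fraction at or above which a site in a
#'   same-lane germline sample is treated as a germline SNP for the
#'   cross-contamination filter. Default 0.25.
#' @param pooled_error_floor Floor applied to the pooled background error rate
#'   so binomial tests are never run at error probability exactly zero.
#'   Default 1e-5.
#' @param use_percentile_rule,use_binomial_rule Switches for the two tracking
#'   criteria (combined conjunctively by default).
#' @param seed Integer seed recorded with the configuration.
#'
#' @return An object of class `run_config`: a validated named list.
#' @seealso [simulation_config()], [read_run_config()]
#' @export
run_config <- function(germline_max_af = 0.005,
                       tumor_min_af = 0.04,
                       tumor_af_inclusive = TRUE,
                       sb_max = 0.9,
                       bf_min_depth = 501L,
                       bf_min_alt_reads = 8L,
                       window_bp = 10L,
                       window_af = 0.20,
                       z_p_max = 1e-18,
                       binomial_alpha = 0.05,
                       track_percentile = 95,
                       track_p = 0.001,
                       track_min_alt_reads = 3L,
                       track_min_depth = 200L,
                       bg_tumor_max_af = 0.025,
                       bg_germline_max_af = 0.005,
                       bg_min_depth_tumor = 250L,
                       bg_min_depth_pbl = 500L,
                       bg_min_depth_plasma = 500L,
                       bg_min_panel = 5L,
                       lane_snp_min_af = 0.25,
                       pooled_error_floor = 1e-5,
                       use_percentile_rule = TRUE,
                       use_binomial_rule = TRUE,
                       seed = 1L) {
  cfg <- list(
    germline_max_af = germline_max_af, tumor_min_af = tumor_min_af,
    tumor_af_inclusive = isTRUE(tumor_af_inclusive), sb_max = sb_max,
    bf_min_depth = as.integer(bf_min_depth),
    bf_min_alt_reads = as.integer(bf_min_alt_reads),
    window_bp = as.integer(window_bp), window_af = window_af,
    z_p_max = z_p_max, binomial_alpha = binomial_alpha,
    track_percentile = track_percentile, track_p = track_p,
    track_min_alt_reads = as.integer(track_min_alt_reads),
    track_min_depth = as.integer(track_min_depth),
    bg_tumor_max_af = bg_tumor_max_af,
    bg_germline_max_af = bg_germline_max_af,
    bg_min_depth_tumor = as.integer(bg_min_depth_tumor),
    bg_min_depth_pbl = as.integer(bg_min_depth_pbl),
    bg_min_depth_plasma = as.integer(bg_min_depth_plasma),
    bg_min_panel = as.integer(bg_min_panel),
    lane_snp_min_af = lane_snp_min_af,
    pooled_error_floor = pooled_error_floor,
    use_percentile_rule = isTRUE(use_percentile_rule),
    use_binomial_rule = isTRUE(use_binomial_rule),
    seed = as.integer(seed))
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  probs <- c("germline_max_af", "tumor_min_af", "window_af", "z_p_max",
             "binomial_alpha", "track_p", "bg_tumor_max_af",
             "bg_germline_max_af", "lane_snp_min_af", "pooled_error_floor")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("run_config: '%s' must be a probability in [0, 1], got %s",
                   p, format(v)), call. = FALSE)
  }
  depths <- c("bf_min_depth", "bf_min_alt_reads", "window_bp",
              "track_min_alt_reads", "track_min_depth", "bg_min_depth_tumor",
              "bg_min_depth_pbl", "bg_min_depth_plasma", "bg_min_panel")
  for (d in depths) {
    v <- cfg[[d]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 || v != round(v))
      stop(sprintf("run_config: '%s' must be a positive integer, got %s",
                   d, format(v)), call. = FALSE)
  }
  if (!(cfg$sb_max > 0.5 && cfg$sb_max <= 1))
    stop("run_config: 'sb_max' must lie in (0.5, 1]", call. = FALSE)
  if (!(cfg$track_percentile > 0 && cfg$track_percentile < 100))
    stop("run_config: 'track_percentile' must lie in (0, 100)", call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Read or write a run configuration
#'
#' Configurations serialize to YAML (or JSON, by file extension) so a run is
#' fully described by a text file plus a seed.
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @param cfg A [run_config()] object.
#' @return `read_run_config()` returns a validated `run_config`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  defaults <- run_config()
  unknown <- setdiff(names(vals), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  vals <- unclass(cfg)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(vals, path)
  }
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("ctDNA run configuration\n")
  for (n in names(x)) cat(sprintf("  %-22s %s\n", n, format(x[[n]])))
  invisible(x)
}
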