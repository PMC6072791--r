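#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the data structure of a targeted deep-sequencing
#' ctDNA study: matched germline (PBL), tumor tissue (FNA) and longitudinal
#' plasma samples per patient; a capture panel of exon-like position blocks;
#' position- and allele-specific background error rates; somatic variants
#' spiked at controlled allele fractions, some absent from the tissue sample
#' (subclonal, plasma-only); germline SNPs shared across a patient's
#' materials; strand-split counts with configurable imbalance; and
#' overdispersed (negative binomial) unique depth around material-specific
#' means.
#'
#' Default mean unique depths are 987x (FNA), 1929x (PBL) and 2227x (plasma),
#' the study-scale values for deduplicated coverage. Background error rates
#' are drawn per (position, alternative allele) from a scaled beta
#' distribution with mean 2e-4, capped at 1e-2; real panels show heterogeneous
#' allele-specific error without a published parametric form, so these
#' defaults are a documented modelling choice (see the package vignette).
#'
#' @param n_patients Number of patients.
#' @param n_positions Panel size in targeted positions (a desk-scale proxy for
#'   a ~499 kb capture design; positions are laid out in 120 bp exon-like
#'   blocks so the proximity-window filter is exercised).
#' @param block_bp Length of each contiguous position block.
#' @param error_shape_a,error_shape_b,error_scale Per-(position, alt) error
#'   rate = `error_scale * Beta(error_shape_a, error_shape_b)`, capped at
#'   0.01. Defaults give mean 2e-4.
#' @param mean_depth Named vector of mean unique depths for FNA, PBL, PLASMA.
#' @param depth_dispersion Negative-binomial size parameter for per-position
#'   depth (larger = tighter).
#' @param variants_per_patient Somatic truth variants spiked per patient.
#' @param fna_af_range Uniform range of true tumor-tissue allele fractions
#'   (driven by tumor purity and clonality).
#' @param plasma_af_range Uniform range of true pretreatment plasma allele
#'   fractions (ctDNA fraction).
#' @param frac_absent_fna Fraction of truth variants absent from the FNA
#'   sample (intra-tumor heterogeneity: detectable in plasma only).
#' @param timepoints_days,ctdna_trajectory,timepoint_status Parallel vectors:
#'   plasma sampling days, the multiplier applied to each variant's base
#'   plasma AF at that timepoint, and the disease-status label attached to the
#'   sample (Dx, CR_PR, SD, PD, NA).
#' @param strand_imbalance Half-width of the per-position forward-strand
#'   probability around 0.5.
#' @param snp_rate Per-position probability that a patient carries a germline
#'   SNP (AF ~ 0.5 heterozygous or 1.0 homozygous, 2:1).
#' @param seed Integer master seed; per-sample substreams are derived
#'   deterministically so adding samples does not perturb existing ones.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_patients = 6L,
                              n_positions = 2000L,
                              block_bp = 120L,
                              error_shape_a = 0.5,
                              error_shape_b = 24.5,
                              error_scale = 0.01,
                              mean_depth = c(FNA = 987, PBL = 1929, PLASMA = 2227),
                              depth_dispersion = 10,
                              variants_per_patient = 3L,
                              fna_af_range = c(0.05, 0.40),
                              plasma_af_range = c(0.005, 0.04),
                              frac_absent_fna = 0.2,
                              timepoints_days = 0L,
                              ctdna_trajectory = 1,
                              timepoint_status = "Dx",
                              strand_imbalance = 0.1,
                              snp_rate = 1e-3,
                              seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_positions = as.integer(n_positions),
              block_bp = as.integer(block_bp),
              error_shape_a = error_shape_a, error_shape_b = error_shape_b,
              error_scale = error_scale,
              mean_depth = mean_depth, depth_dispersion = depth_dispersion,
              variants_per_patient = as.integer(variants_per_patient),
              fna_af_range = fna_af_range, plasma_af_range = plasma_af_range,
              frac_absent_fna = frac_absent_fna,
              timepoints_days = as.integer(timepoints_days),
              ctdna_trajectory = ctdna_trajectory,
              timepoint_status = as.character(timepoint_status),
              strand_imbalance = strand_imbalance, snp_rate = snp_rate,
              seed = as.integer(seed))
  stopifnot(cfg$n_patients >= 1, cfg$n_positions >= 1,
            all(cfg$mean_depth > 0), cfg$depth_dispersion > 0)
  if (cfg$error_scale < 0 || cfg$error_shape_a <= 0 || cfg$error_shape_b <= 0)
    stop("simulation_config: error-rate parameters must be positive",
         call. = FALSE)
  if (cfg$frac_absent_fna < 0 || cfg$frac_absent_fna > 1 ||
      cfg$snp_rate < 0 || cfg$snp_rate > 1)
    stop("simulation_config: fractions must lie in [0, 1]", call. = FALSE)
  if (cfg$strand_imbalance < 0 || cfg$strand_imbalance >= 0.5)
    stop("simulation_config: strand_imbalance must lie in [0, 0.5)",
         call. = FALSE)
  if (length(cfg$ctdna_trajectory) != length(cfg$timepoints_days) ||
      length(cfg$timepoint_status) != length(cfg$timepoints_days))
    stop("simulation_config: timepoints_days, ctdna_trajectory and ",
         "timepoint_status must have equal length", call. = FALSE)
  structure(cfg, class = "simulation_config")
}

# Deterministic substream seed (< 2^31) from a master seed and an index.
substream_seed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 65011 + 1) * 30011 +
               (as.numeric(index) %% 65011) * 17) %% 2147483647L
}

with_substream <- function(seed, index, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, index))
  expr
}

#' Simulate the per-site background error model shared by a batch of samples
#'
#' Sequencing and library-preparation error is a property of the assay and
#' position, not of the sample: all samples simulated against the same error
#' model share its per-(position, alternative allele) rates, which is what
#' makes a background panel informative about a held-out sample.
#'
#' @param cfg A [simulation_config()].
#' @param seed Seed for the error-model draw (defaults to the config seed).
#' @return An `error_model`: data frame with `chrom`, `pos`, `ref`, `alt`,
#'   `rate` (3 rows per position) plus per-position forward-strand
#'   probabilities as an attribute.
#' @export
simulate_error_model <- function(cfg = simulation_config(), seed = cfg$seed) {
  n <- cfg$n_positions
  with_substream(seed, 0L, {
    nblock <- ceiling(n / cfg$block_bp)
    starts <- cumsum(c(1, rep(cfg$block_bp + 10000L, nblock - 1)))
    pos <- unlist(lapply(seq_len(nblock), function(b)
      starts[b] + seq_len(min(cfg$block_bp, n - (b - 1) * cfg$block_bp)) - 1L))
    ref <- sample(BASES, n, replace = TRUE)
    rate <- pmin(cfg$error_scale *
                   stats::rbeta(3L * n, cfg$error_shape_a, cfg$error_shape_b),
                 0.01)
    p_strand <- 0.5 + stats::runif(n, -cfg$strand_imbalance,
                                   cfg$strand_imbalance)
    idx <- rep(seq_len(n), each = 4L)
    base <- rep(BASES, times = n)
    keep <- base != ref[idx]
    em <- data.frame(chrom = "chr1", pos = pos[idx][keep], ref = ref[idx][keep],
                     alt = base[keep], rate = rate, stringsAsFactors = FALSE)
    structure(em, p_strand = p_strand,
              positions = data.frame(chrom = "chr1", pos = pos, ref = ref,
                                     stringsAsFactors = FALSE),
              class = c("error_model", "data.frame"))
  })
}

# Draw one sample's pileup given the shared error model.
# true_af: optional named numeric vector keyed by "chrom:pos:alt" overriding
# the error rate at spiked sites.
sim_sample <- function(em, mean_depth, dispersion, true_af = NULL,
                       sample_id = "sample") {
  posdf <- attr(em, "positions")
  p_strand <- attr(em, "p_strand")
  n <- nrow(posdf)
  depth <- stats::rnbinom(n, mu = mean_depth, size = dispersion)
  af <- em$rate
  if (!is.null(true_af) && length(true_af) > 0) {
    i <- match(names(true_af), site_key(em$chrom, em$pos, em$alt))
    if (anyNA(i))
      stop("spiked variant outside the simulated panel: ",
           paste(names(true_af)[is.na(i)], collapse = ", "), call. = FALSE)
    af[i] <- true_af
  }
  idx <- match(paste(em$chrom, em$pos), paste(posdf$chrom, posdf$pos))
  alt_counts <- stats::rbinom(length(af), depth[idx], af)
  # guard: total non-reference reads cannot exceed depth
  tot_alt <- rowsum(alt_counts, idx)[, 1]
  over <- which(tot_alt > depth)
  for (i in over) {
    j <- which(idx == i)
    excess <- tot_alt[i] - depth[i]
    k <- j[which.max(alt_counts[j])]
    alt_counts[k] <- alt_counts[k] - excess
  }
  ref_counts <- depth - rowsum(alt_counts, idx)[, 1]
  counts <- matrix(0L, n, 8L, dimnames = list(NULL, COUNT_COLS))
  ref_fwd <- stats::rbinom(n, ref_counts, p_strand)
  ri <- match(posdf$ref, BASES)
  counts[cbind(seq_len(n), 2L * ri - 1L)] <- ref_fwd
  counts[cbind(seq_len(n), 2L * ri)] <- as.integer(ref_counts - ref_fwd)
  alt_fwd <- stats::rbinom(length(alt_counts), alt_counts, p_strand[idx])
  ai <- match(em$alt, BASES)
  counts[cbind(idx, 2L * ai - 1L)] <-
    counts[cbind(idx, 2L * ai - 1L)] + as.integer(alt_fwd)
  counts[cbind(idx, 2L * ai)] <-
    counts[cbind(idx, 2L * ai)] + as.integer(alt_counts - alt_fwd)
  pileup_table(posdf$chrom, posdf$pos, posdf$ref, counts,
               sample_id = sample_id)
}

# Germline SNP allele fractions for one patient: named vector keyed by site.
sim_snps <- function(em, snp_rate) {
  hit <- which(stats::runif(nrow(em)) < snp_rate / 3)
  if (length(hit) == 0) return(stats::setNames(numeric(0), character(0)))
  af <- ifelse(stats::runif(length(hit)) < 2 / 3, 0.5, 1.0)
  stats::setNames(af, site_key(em$chrom[hit], em$pos[hit], em$alt[hit]))
}

#' Simulate a matched PBL/FNA/plasma cohort with ground truth
#'
#' For each patient, generates one germline (PBL) sample, one tumor-tissue
#' (FNA) sample and one plasma sample per configured timepoint, all over the
#' same panel and sharing the same per-site error model. Somatic truth
#' variants are spiked at tissue allele fractions in `fna_af_range` and plasma
#' fractions in `plasma_af_range` scaled by the per-timepoint ctDNA
#' trajectory; a configurable fraction of them are absent from the FNA
#' (plasma-only subclones). Germline SNPs appear in every material of the
#' carrier patient. Identical configuration and seed reproduce the cohort
#' byte for byte.
#'
#' @param cfg A [simulation_config()].
#' @return A list with `sheet` (a [sample_sheet()]), `pileups` (named list of
#'   [pileup_table()]), `truth` (variant-level data frame: patient, site,
#'   consequence, `in_fna`, base allele fractions) and `truth_af` (long data
#'   frame of true allele fraction per sample and site).
#' @export
simulate_cohort <- function(cfg = simulation_config()) {
  em <- simulate_error_model(cfg)
  n_tp <- length(cfg$timepoints_days)
  patients <- sprintf("P%02d", seq_len(cfg$n_patients))

  truth_list <- list()
  snp_list <- list()
  with_substream(cfg$seed, 1L, {
    for (pi in seq_along(patients)) {
      snp_list[[pi]] <- sim_snps(em, cfg$snp_rate)
      k <- cfg$variants_per_patient
      if (k > 0) {
        # somatic truth sites never coincide with the patient's own SNPs
        snp_rows <- match(names(snp_list[[pi]]),
                          site_key(em$chrom, em$pos, em$alt))
        rows <- sample(setdiff(seq_len(nrow(em)), snp_rows), k)
        truth_list[[pi]] <- data.frame(
          patient_id = patients[pi],
          chrom = em$chrom[rows], pos = em$pos[rows], ref = em$ref[rows],
          alt = em$alt[rows],
          consequence = sample(DELETERIOUS, k, replace = TRUE,
                               prob = c(0.75, 0.1, 0.05, 0.1)),
          in_fna = stats::runif(k) >= cfg$frac_absent_fna,
          fna_af = stats::runif(k, cfg$fna_af_range[1], cfg$fna_af_range[2]),
          plasma_af = stats::runif(k, cfg$plasma_af_range[1],
                                   cfg$plasma_af_range[2]),
          stringsAsFactors = FALSE)
      }
    }
  })
  truth <- if (length(truth_list) > 0) do.call(rbind, truth_list) else
    data.frame(patient_id = character(), chrom = character(), pos = integer(),
               ref = character(), alt = character(), consequence = character(),
               in_fna = logical(), fna_af = numeric(), plasma_af = numeric(),
               stringsAsFactors = FALSE)
  if (nrow(truth) > 0) truth$fna_af[!truth$in_fna] <- 0

  sheet_rows <- list()
  pileups <- list()
  truth_af_rows <- list()
  lane_size <- 8L
  n_slots <- 2L + n_tp
  sample_counter <- 0L
  for (pi in seq_along(patients)) {
    pat <- patients[pi]
    tv <- truth[truth$patient_id == pat, , drop = FALSE]
    tkey <- if (nrow(tv) > 0) site_key(tv$chrom, tv$pos, tv$alt) else character(0)
    snps <- snp_list[[pi]]
    specs <- list(list(slot = 1L, material = "PBL",
                       id = sprintf("%s_PBL", pat), tp = NA_integer_,
                       af = snps, mass = 200),
                  list(slot = 2L, material = "FNA",
                       id = sprintf("%s_FNA", pat), tp = NA_integer_,
                       af = c(snps, stats::setNames(tv$fna_af, tkey)),
                       mass = NA_real_))
    for (ti in seq_len(n_tp)) {
      specs[[2L + ti]] <- list(
        slot = 2L + ti, material = "PLASMA",
        id = sprintf("%s_T%03d", pat, cfg$timepoints_days[ti]),
        tp = cfg$timepoints_days[ti],
        af = c(snps, stats::setNames(tv$plasma_af * cfg$ctdna_trajectory[ti],
                                     tkey)),
        mass = NA_real_)
    }
    for (sp in specs) {
      sample_counter <- sample_counter + 1L
      stream <- (pi - 1L) * 64L + sp$slot
      mass <- sp$mass
      pl <- with_substream(cfg$seed, 1000L + stream, {
        if (sp$material == "PLASMA")
          mass <- round(stats::rlnorm(1, log(30), 0.5), 2)
        af <- sp$af[sp$af > 0]
        af <- af[!duplicated(names(af))]
        sim_sample(em, cfg$mean_depth[[sp$material]], cfg$depth_dispersion,
                   true_af = af, sample_id = sp$id)
      })
      pileups[[sp$id]] <- pl
      status <- if (sp$material == "PLASMA")
        cfg$timepoint_status[match(sp$tp, cfg$timepoints_days)] else
          NA_character_
      sheet_rows[[sample_counter]] <- data.frame(
        sample_id = sp$id, patient_id = pat, material = sp$material,
        timepoint_days = sp$tp,
        lane_batch = sprintf("L%02d", (sample_counter - 1L) %/% lane_size + 1L),
        input_dna_ng = mass, disease_status = status,
        stringsAsFactors = FALSE)
      if (nrow(tv) > 0) {
        af_here <- switch(sp$material,
                          PBL = rep(0, nrow(tv)),
                          FNA = tv$fna_af,
                          PLASMA = tv$plasma_af *
                            cfg$ctdna_trajectory[match(sp$tp,
                                                       cfg$timepoints_days)])
        truth_af_rows[[length(truth_af_rows) + 1L]] <- data.frame(
          sample_id = sp$id, chrom = tv$chrom, pos = tv$pos, ref = tv$ref,
          alt = tv$alt, true_af = af_here, stringsAsFactors = FALSE)
      }
    }
  }
  sheet_df <- do.call(rbind, sheet_rows)
  sheet <- sample_sheet(sheet_df[, SHEET_COLS])
  sheet$disease_status <- sheet_df$disease_status
  truth_af <- if (length(truth_af_rows) > 0) do.call(rbind, truth_af_rows) else
    data.frame(sample_id = character(), chrom = character(), pos = integer(),
               ref = character(), alt = character(), true_af = numeric(),
               stringsAsFactors = FALSE)
  list(sheet = sheet, pileups = pileups, truth = truth, truth_af = truth_af,
       error_model = em)
}

#' Simulate a reference-standard dilution series
#'
#' Emulates a commercial cfDNA reference standard carrying a small set of
#' hotspot SNVs at fixed allele fractions (e.g. 0.1%, 1% and 5%): one
#' plasma-like pileup per dilution level with `n_variants` sites spiked at
#' that level over the shared background error model, plus a matched
#' error-only germline pileup. Spiked sites are spaced more than the
#' proximity-window width apart, as hotspots in distinct genes are.
#'
#' @param levels Numeric vector of spike-in allele fractions in (0, 1), or 0
#'   for an error-only control.
#' @param n_variants Number of spiked hotspot SNVs per level.
#' @param depth Mean unique depth of the reference-standard libraries.
#' @param seed Integer seed.
#' @param n_positions Panel size.
#' @param depth_dispersion Negative-binomial size for depth (reference
#'   material is a uniform library, so the default is tight).
#' @param error_model Optional shared [simulate_error_model()] object; drawn
#'   from `seed` when NULL.
#' @return List with `pileups` (one per level, named by level), `germline`,
#'   `truth` (site table with the spiked level per pileup) and `error_model`.
#' @export
simulate_reference_standard <- function(levels, n_variants = 6L, depth = 2000,
                                        seed = 1L, n_positions = 1500L,
                                        depth_dispersion = 100,
                                        error_model = NULL) {
  stopifnot(n_variants >= 1, all(levels >= 0), all(levels < 1))
  cfg <- simulation_config(n_positions = n_positions, seed = as.integer(seed))
  em <- if (is.null(error_model)) simulate_error_model(cfg) else error_model
  truth <- with_substream(seed, 7L, {
    rows <- round(seq(1, nrow(em), length.out = n_variants + 2))[
      2:(n_variants + 1)]
    data.frame(chrom = em$chrom[rows], pos = em$pos[rows], ref = em$ref[rows],
               alt = em$alt[rows], consequence = "nonsynonymous",
               stringsAsFactors = FALSE)
  })
  tkey <- site_key(truth$chrom, truth$pos, truth$alt)
  pileups <- list()
  for (li in seq_along(levels)) {
    lv <- levels[li]
    id <- sprintf("REF_%g", lv)
    pileups[[id]] <- with_substream(seed, 100L + li, {
      af <- stats::setNames(rep(lv, n_variants), tkey)
      sim_sample(em, depth, depth_dispersion,
                 true_af = af[af > 0], sample_id = id)
    })
  }
  germline <- with_substream(seed, 99L, {
    sim_sample(em, depth, depth_dispersion, sample_id = "REF_germline")
  })
  list(pileups = pileups, germline = germline, truth = truth,
       error_model = em)
}

#' Simulate an error-only plasma background panel
#'
#' Draws `n_samples` plasma-like pileups carrying only background error over a
#' shared error model, for use as the cross-plasma background panel of the
#' z-test and the tracking percentile rule.
#'
#' @param n_samples Number of panel samples.
#' @param error_model A [simulate_error_model()] object.
#' @param depth Mean unique depth.
#' @param seed Integer seed.
#' @param depth_dispersion Negative-binomial size for depth.
#' @param prefix Sample-id prefix.
#' @return Named list of [pileup_table()]s.
#' @export
simulate_plasma_panel <- function(n_samples, error_model, depth = 2227,
                                  seed = 1L, depth_dispersion = 10,
                                  prefix = "BG") {
  stopifnot(n_samples >= 1)
  out <- list()
  for (i in seq_len(n_samples)) {
    id <- sprintf("%s%02d", prefix, i)
    out[[id]] <- with_substream(seed, 500L + i, {
      sim_sample(error_model, depth, depth_dispersion, sample_id = id)
    })
  }
  out
}

#' Simulate technical replicate pairs for the false-positive assay
#'
#' Each pair is two independent draws from the same germline DNA: identical
#' per-position error rates, independent sampling noise, and no somatic truth
#' variants. Treating one member as a mock plasma sample and the other as its
#' matched germline measures the false-discovery behaviour of the biopsy-free
#' caller on pure technical background.
#'
#' @param n_pairs Number of replicate pairs.
#' @param cfg A [simulation_config()] (panel size and error model defaults).
#' @param seed Integer seed (defaults to the config seed).
#' @param depth Mean unique depth per member (defaults to the PBL mean).
#' @param error_model Optional shared error model.
#' @return List of `n_pairs` lists with elements `a` and `b`; the (empty)
#'   truth table is attached as an attribute.
#' @export
simulate_replicate_pairs <- function(n_pairs, cfg = simulation_config(),
                                     seed = cfg$seed,
                                     depth = cfg$mean_depth[["PBL"]],
                                     error_model = NULL) {
  stopifnot(n_pairs >= 1)
  em <- if (is.null(error_model))
    simulate_error_model(cfg, seed = seed) else error_model
  pairs <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    pairs[[i]] <- with_substream(seed, 2000L + i, {
      list(a = sim_sample(em, depth, cfg$depth_dispersion,
                          sample_id = sprintf("REP%02d_A", i)),
           b = sim_sample(em, depth, cfg$depth_dispersion,
                          sample_id = sprintf("REP%02d_B", i)))
    })
  }
  attr(pairs, "truth") <- data.frame(chrom = character(), pos = integer(),
                                     ref = character(), alt = character(),
                                     stringsAsFactors = FALSE)
  attr(pairs, "error_model") <- em
  pairs
}
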