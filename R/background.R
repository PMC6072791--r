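#' Strand bias of a position
#'
#' Defined as the fraction of total position depth carried by the majority
#' strand, so perfectly balanced coverage gives 0.5 and single-strand
#' coverage gives 1. Positions pass the gate only when strand bias is
#' strictly below the configured maximum (default 0.9).
#'
#' @param fwd,rev Read counts on the forward and reverse strand over all
#'   alleles at the position.
#' @return Numeric in [0.5, 1]; errors on zero total depth (the position is
#'   then skipped upstream).
#' @examples
#' strand_bias(50, 50)  # 0.5
#' strand_bias(95, 5)   # 0.95, fails the < 0.9 gate
#' @export
strand_bias <- function(fwd, rev) {
  if (any(fwd < 0 | rev < 0)) stop("strand_bias: negative counts",
                                   call. = FALSE)
  tot <- fwd + rev
  if (any(tot == 0))
    stop("strand_bias: undefined at zero depth", call. = FALSE)
  pmax(fwd, rev) / tot
}

#' Empirical percentile with linear interpolation
#'
#' The percentile convention used by the tracking rule: linear interpolation
#' between order statistics (the rank of the q-th percentile of n values is
#' `(n - 1) * q/100 + 1`). For 1..100 the 95th percentile is 95.05.
#'
#' @param values Non-empty numeric vector.
#' @param q Percentile in (0, 100).
#' @return The empirical q-th percentile.
#' @export
empirical_percentile <- function(values, q) {
  if (length(values) == 0) stop("empirical_percentile: empty input",
                                call. = FALSE)
  if (any(is.na(values))) stop("empirical_percentile: NA values",
                               call. = FALSE)
  if (!(q > 0 && q < 100)) stop("empirical_percentile: q must lie in (0, 100)",
                                call. = FALSE)
  unname(stats::quantile(values, q / 100, type = 7, names = FALSE))
}

# Row-wise linear-interpolation percentile of a matrix with NA-masked cells.
# Same convention as empirical_percentile(); returns NA for all-NA rows.
row_percentile <- function(A, q) {
  nr <- nrow(A)
  if (nr == 0) return(numeric(0))
  n <- rowSums(!is.na(A))
  o <- order(row(A), A, na.last = TRUE)
  s <- matrix(A[o], nrow = nr, byrow = TRUE)
  h <- (n - 1) * q / 100 + 1
  j <- pmax(floor(h), 1)
  g <- h - j
  ridx <- seq_len(nr)
  lo <- s[cbind(ridx, pmin(j, ncol(A)))]
  hi <- s[cbind(ridx, pmin(j + 1, ncol(A)))]
  hi[is.na(hi)] <- lo[is.na(hi)]
  out <- lo + g * (hi - lo)
  out[n == 0] <- NA_real_
  out
}

#' Build the per-site cross-plasma background model
#'
#' For every (position, alternative allele) of the panel, collects the allele
#' fractions observed in a set of other plasma samples ("the background
#' panel") and summarizes them into the quantities the somatic tests need:
#' the panel mean and standard deviation (z-test), the empirical 95th
#' percentile (tumor-informed tracking rule) and the pooled error rate
#' (total alt reads over total depth; binomial tests).
#'
#' A panel sample contributes its allele fraction at a site only when all
#' inclusion filters hold: its own plasma depth is at least
#' `cfg$bg_min_depth_plasma` (500), the paired tumor sample carries the
#' allele below `cfg$bg_tumor_max_af` (2.5%) at depth at least 250, and the
#' paired germline carries it below `cfg$bg_germline_max_af` (0.5%) at depth
#' at least 500 — so real somatic or germline signal in a panel member does
#' not contaminate the error model. A missing paired tumor or germline pileup
#' leaves that filter passing (no evidence of non-error signal).
#'
#' Sites with fewer than `cfg$bg_min_panel` contributing samples are marked
#' untestable for the z-test (`n` below the minimum); the tracking rule then
#' falls back to a binomial test at the pooled error rate.
#'
#' @param panel Named list of plasma [pileup_table()]s over identical panel
#'   positions. Must exclude the sample under test (see `exclude_sample`).
#' @param tumor,germline Optional named lists of paired tumor / germline
#'   pileups, keyed by the panel sample names; entries may be NULL.
#' @param cfg A [run_config()].
#' @param exclude_sample Sample name(s) removed from `panel` before building
#'   (the sample under test must never inform its own background).
#' @return A `background_model`: data frame with `chrom`, `pos`, `ref`,
#'   `alt`, `n`, `mean_af`, `sd_af`, `q95_af`, `pooled_error`, with the mean
#'   panel depth attached as an attribute (used for the z-test sd floor).
#' @export
build_background <- function(panel, tumor = NULL, germline = NULL,
                             cfg = run_config(), exclude_sample = NULL) {
  if (is.null(names(panel)))
    names(panel) <- vapply(panel, pileup_sample_id, character(1))
  panel <- panel[!names(panel) %in% exclude_sample]
  if (length(panel) == 0)
    stop("build_background: empty panel after exclusions", call. = FALSE)
  ref_long <- pileup_long(panel[[1]])
  key0 <- site_key(ref_long$chrom, ref_long$pos, ref_long$alt)
  ns <- length(panel)
  nr <- nrow(ref_long)
  A <- matrix(NA_real_, nr, ns)
  alt_sum <- numeric(nr)
  dep_sum <- numeric(nr)
  nvec <- integer(nr)
  dep_all <- 0
  for (si in seq_len(ns)) {
    s <- names(panel)[si]
    pl <- if (si == 1) ref_long else pileup_long(panel[[si]])
    if (si > 1 &&
        !identical(site_key(pl$chrom, pl$pos, pl$alt), key0))
      stop("build_background: panel sample '", s,
           "' covers different positions than the rest of the panel",
           call. = FALSE)
    inc <- pl$depth >= cfg$bg_min_depth_plasma
    tp <- tumor[[s]]
    if (!is.null(tp)) {
      tl <- pileup_long(tp)
      ti <- match(key0, site_key(tl$chrom, tl$pos, tl$alt))
      t_af <- tl$af[ti]
      t_dep <- tl$depth[ti]
      inc <- inc & !is.na(ti) & t_dep >= cfg$bg_min_depth_tumor &
        t_af < cfg$bg_tumor_max_af
    }
    gp <- germline[[s]]
    if (!is.null(gp)) {
      gl <- pileup_long(gp)
      gi <- match(key0, site_key(gl$chrom, gl$pos, gl$alt))
      g_af <- gl$af[gi]
      g_dep <- gl$depth[gi]
      inc <- inc & !is.na(gi) & g_dep >= cfg$bg_min_depth_pbl &
        g_af < cfg$bg_germline_max_af
    }
    A[inc, si] <- pl$af[inc]
    alt_sum[inc] <- alt_sum[inc] + pl$alt_reads[inc]
    dep_sum[inc] <- dep_sum[inc] + pl$depth[inc]
    nvec <- nvec + inc
    dep_all <- dep_all + mean(pl$depth)
  }
  mean_af <- rowMeans(A, na.rm = TRUE)
  mean_af[nvec == 0] <- NA_real_
  s2 <- rowSums(A^2, na.rm = TRUE)
  sd_af <- ifelse(nvec >= 2,
                  sqrt(pmax(0, (s2 - nvec * mean_af^2) / (nvec - 1))), 0)
  sd_af[nvec == 0] <- NA_real_
  q95 <- row_percentile(A, cfg$track_percentile)
  out <- data.frame(chrom = ref_long$chrom, pos = ref_long$pos,
                    ref = ref_long$ref, alt = ref_long$alt,
                    n = nvec, mean_af = mean_af, sd_af = sd_af,
                    q95_af = q95,
                    pooled_error = ifelse(dep_sum > 0, alt_sum / dep_sum, 0),
                    stringsAsFactors = FALSE)
  structure(out, panel_mean_depth = dep_all / ns,
            panel_samples = names(panel),
            class = c("background_model", "data.frame"))
}

#' Read or write a background model TSV
#'
#' Serializes the per-site background statistics for reuse across runs.
#' Columns: `chrom`, `pos`, `ref`, `alt`, `n`, `mean_af`, `sd_af`, `q95_af`,
#' `pooled_error`; the panel mean depth travels in a '#'-prefixed header
#' comment.
#'
#' @param bg A `background_model`.
#' @param path File path.
#' @return `read_background()` returns a `background_model`;
#'   `write_background()` returns `path` invisibly.
#' @export
write_background <- function(bg, path) {
  stopifnot(inherits(bg, "background_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#panel_mean_depth=%.6f", attr(bg, "panel_mean_depth")),
             con)
  utils::write.table(as.data.frame(bg), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_background
#' @export
read_background <- function(path) {
  if (!file.exists(path)) stop("background file not found: ", path,
                               call. = FALSE)
  first <- readLines(path, n = 1L)
  pmd <- as.numeric(sub("^#panel_mean_depth=", "", first))
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                          stringsAsFactors = FALSE, comment.char = "")
  structure(df, panel_mean_depth = pmd,
            class = c("background_model", "data.frame"))
}
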