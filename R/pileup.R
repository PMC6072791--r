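#' @keywords internal
"_PACKAGE"

BASES <- c("A", "C", "G", "T")
COUNT_COLS <- paste0(rep(BASES, each = 2L), "_", c("fwd", "rev"))
FWD_COLS <- paste0(BASES, "_fwd")
REV_COLS <- paste0(BASES, "_rev")

site_key <- function(chrom, pos, alt) paste(chrom, pos, alt, sep = ":")

#' Construct a per-position strand-split allele-count table
#'
#' The substrate of every statistical test in the package: for each targeted
#' position, the number of Q30-filtered unique reads supporting each of the
#' four bases on each strand. Counts are assumed to be deduplicated and
#' quality-filtered upstream (base quality Phred >= 30).
#'
#' @param chrom Character vector of contig names.
#' @param pos 1-based integer positions, strictly increasing within a contig.
#' @param ref Reference base at each position, one of A/C/G/T.
#' @param counts Matrix or data frame with the eight columns
#'   `A_fwd, A_rev, C_fwd, C_rev, G_fwd, G_rev, T_fwd, T_rev` of non-negative
#'   integer read counts.
#' @param sample_id Sample identifier attached to the table.
#' @return A `pileup_table`: a data frame with columns `chrom`, `pos`, `ref`
#'   and the eight count columns, with the sample id as an attribute.
#' @examples
#' p <- pileup_table("chr1", 1:3, c("A", "C", "G"),
#'                   matrix(5L, 3, 8, dimnames = list(NULL, plasmatrack:::COUNT_COLS)),
#'                   sample_id = "S1")
#' pileup_depth(p)
#' @export
pileup_table <- function(chrom, pos, ref, counts, sample_id = "sample") {
  counts <- as.data.frame(counts)
  if (!all(COUNT_COLS %in% names(counts)))
    stop("counts must contain columns: ", paste(COUNT_COLS, collapse = ", "),
         call. = FALSE)
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = as.character(ref), stringsAsFactors = FALSE)
  for (cc in COUNT_COLS) df[[cc]] <- as.integer(counts[[cc]])
  validate_pileup(df, sample_id = sample_id)
}

validate_pileup <- function(df, sample_id = "sample", source = "pileup") {
  need <- c("chrom", "pos", "ref", COUNT_COLS)
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop(sprintf("%s: missing column(s): %s", source,
                 paste(miss, collapse = ", ")), call. = FALSE)
  df <- df[, need]
  bad_ref <- which(!df$ref %in% BASES)
  if (length(bad_ref) > 0)
    stop(sprintf("%s: non-ACGT ref '%s' at row %d", source,
                 df$ref[bad_ref[1]], bad_ref[1]), call. = FALSE)
  for (cc in COUNT_COLS) {
    v <- df[[cc]]
    bad <- which(is.na(v) | v < 0)
    if (length(bad) > 0)
      stop(sprintf("%s: negative or missing count in column '%s' at row %d",
                   source, cc, bad[1]), call. = FALSE)
  }
  key <- paste(df$chrom, df$pos)
  if (anyDuplicated(key))
    stop(sprintf("%s: duplicate (chrom, pos) at row %d", source,
                 anyDuplicated(key)), call. = FALSE)
  for (ch in unique(df$chrom)) {
    p <- df$pos[df$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop(sprintf("%s: positions not strictly increasing on %s", source, ch),
           call. = FALSE)
  }
  structure(df, sample_id = sample_id,
            class = c("pileup_table", "data.frame"))
}

#' @rdname pileup_table
#' @param p A `pileup_table`.
#' @export
pileup_depth <- function(p) {
  unname(rowSums(as.matrix(p[, COUNT_COLS])))
}

#' Sample identifier of a pileup table
#' @param p A `pileup_table`.
#' @return The sample id string.
#' @export
pileup_sample_id <- function(p) attr(p, "sample_id")

#' Expand a pileup to per-(position, alternative allele) records
#'
#' Each position yields three candidate non-reference alleles, each an
#' independent hypothesis for the somatic tests. Depth and strand bias are
#' position-level (over all reads); `alt_reads` and `af` are allele-level.
#' Strand bias is the majority-strand fraction of total depth, in [0.5, 1],
#' undefined (NA) at zero depth.
#'
#' @param p A `pileup_table`.
#' @return Data frame with columns `chrom`, `pos`, `ref`, `alt`, `alt_fwd`,
#'   `alt_rev`, `alt_reads`, `depth`, `af`, `sb` (3 rows per position).
#' @export
pileup_long <- function(p) {
  n <- nrow(p)
  m <- as.matrix(p[, COUNT_COLS])
  depth <- rowSums(m)
  fwd <- rowSums(m[, FWD_COLS, drop = FALSE])
  rev <- rowSums(m[, REV_COLS, drop = FALSE])
  sb <- ifelse(depth > 0, pmax(fwd, rev) / depth, NA_real_)
  base_fwd <- m[, FWD_COLS, drop = FALSE]
  base_rev <- m[, REV_COLS, drop = FALSE]
  idx <- rep(seq_len(n), each = 4L)
  base <- rep(BASES, times = n)
  keep <- base != p$ref[idx]
  idx <- idx[keep]
  base <- base[keep]
  bi <- match(base, BASES)
  af_den <- depth[idx]
  alt_fwd <- base_fwd[cbind(idx, bi)]
  alt_rev <- base_rev[cbind(idx, bi)]
  alt_reads <- alt_fwd + alt_rev
  data.frame(
    chrom = p$chrom[idx], pos = p$pos[idx], ref = p$ref[idx], alt = base,
    alt_fwd = alt_fwd, alt_rev = alt_rev, alt_reads = alt_reads,
    depth = depth[idx],
    af = ifelse(af_den > 0, alt_reads / af_den, 0),
    sb = sb[idx],
    stringsAsFactors = FALSE)
}

#' Read and write pileup TSV files
#'
#' Dialect: a single '#'-prefixed header line naming the columns
#' `chrom pos ref A_fwd A_rev C_fwd C_rev G_fwd G_rev T_fwd T_rev`, then one
#' tab-separated row per targeted position. Malformed input (missing columns,
#' negative counts, duplicate positions, non-ACGT reference) raises an error
#' naming the offending line or column.
#'
#' @param path File path.
#' @param sample_id Sample id to attach; defaults to the file name without
#'   extension.
#' @return `read_pileup()` returns a validated [pileup_table()];
#'   `write_pileup()` returns `path` invisibly.
#' @export
read_pileup <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("pileup file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#"))
    stop("pileup format error in ", path,
         ": first line must be a '#'-prefixed header", call. = FALSE)
  cols <- strsplit(sub("^#", "", header), "\t", fixed = TRUE)[[1]]
  need <- c("chrom", "pos", "ref", COUNT_COLS)
  miss <- setdiff(need, cols)
  if (length(miss) > 0)
    stop("pileup format error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  df <- utils::read.table(path, sep = "\t", skip = 1L, header = FALSE,
                          col.names = cols, stringsAsFactors = FALSE,
                          comment.char = "")
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  # validation reports data-row indices; +1 converts to file line numbers
  tryCatch(
    validate_pileup(df, sample_id = sample_id, source = basename(path)),
    error = function(e) {
      msg <- conditionMessage(e)
      m <- regmatches(msg, regexpr("row [0-9]+", msg))
      if (length(m) == 1L) {
        r <- as.integer(sub("row ", "", m))
        msg <- paste0(msg, sprintf(" [file line %d]", r + 1L))
      }
      stop(msg, call. = FALSE)
    })
}

#' @rdname read_pileup
#' @param p A `pileup_table`.
#' @export
write_pileup <- function(p, path) {
  stopifnot(inherits(p, "pileup_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(c("chrom", "pos", "ref", COUNT_COLS),
                               collapse = "\t")), con)
  utils::write.table(as.data.frame(p), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.pileup_table <- function(x, ...) {
  cat(sprintf("pileup_table '%s': %d positions, %d contig(s), mean depth %.1f\n",
              pileup_sample_id(x), nrow(x), length(unique(x$chrom)),
              mean(pileup_depth(x))))
  NextMethod()
}
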