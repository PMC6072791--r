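SHEET_COLS <- c("sample_id", "patient_id", "material", "timepoint_days",
                "lane_batch", "input_dna_ng")
MATERIALS <- c("PBL", "FNA", "PLASMA")

#' Construct and validate a sample sheet
#'
#' Links samples to patients, materials (PBL germline, FNA tumor tissue,
#' plasma), longitudinal timepoints, flow-cell lane batches (used by the
#' cross-contamination SNP filter) and plasma input DNA mass (which caps the
#' attainable unique depth and hence the limit of detection).
#'
#' Validation enforces unique sample ids, known materials, non-empty lane
#' batches, and that every patient with a plasma or FNA sample also has at
#' least one PBL (matched germline) sample.
#'
#' @param df Data frame with columns `sample_id`, `patient_id`, `material`
#'   (PBL/FNA/PLASMA), `timepoint_days` (integer or NA), `lane_batch`,
#'   `input_dna_ng` (positive or NA).
#' @return A validated `sample_sheet` data frame.
#' @export
sample_sheet <- function(df) {
  miss <- setdiff(SHEET_COLS, names(df))
  if (length(miss) > 0)
    stop("sample sheet: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(df)[, SHEET_COLS]
  df$sample_id <- as.character(df$sample_id)
  df$patient_id <- as.character(df$patient_id)
  df$material <- as.character(df$material)
  df$timepoint_days <- as.integer(df$timepoint_days)
  df$lane_batch <- as.character(df$lane_batch)
  df$input_dna_ng <- as.numeric(df$input_dna_ng)
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup) > 0)
    stop("sample sheet: duplicate sample_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(df$material), MATERIALS)
  if (length(bad) > 0)
    stop("sample sheet: unknown material: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(is.na(df$lane_batch) | !nzchar(df$lane_batch)))
    stop("sample sheet: lane_batch must be non-empty for every sample",
         call. = FALSE)
  if (any(!is.na(df$input_dna_ng) & df$input_dna_ng <= 0))
    stop("sample sheet: input_dna_ng must be positive where given",
         call. = FALSE)
  pbl_patients <- unique(df$patient_id[df$material == "PBL"])
  needs <- unique(df$patient_id[df$material %in% c("PLASMA", "FNA")])
  orphans <- setdiff(needs, pbl_patients)
  if (length(orphans) > 0)
    stop("sample sheet: patient(s) with plasma/FNA but no PBL germline: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  structure(df, class = c("sample_sheet", "data.frame"))
}

#' Read or write a sample sheet TSV
#'
#' @param path Tab-separated file with a header row naming the sample-sheet
#'   columns.
#' @param sheet A [sample_sheet()].
#' @return `read_sample_sheet()` returns a validated `sample_sheet`;
#'   `write_sample_sheet()` returns `path` invisibly.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "",
                          na.strings = c("NA", ""))
  sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(sheet, path) {
  stopifnot(inherits(sheet, "sample_sheet"))
  utils::write.table(as.data.frame(sheet), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
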