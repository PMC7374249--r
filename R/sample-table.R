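DRUGS <- c("pred", "cyc", "tac", "aza", "mmf")
DOSE_COLS <- paste0("dose_", DRUGS)

drug_on <- function(samples, drug) {
  switch(drug,
         pred = samples$pred == "on",
         cyc  = samples$cni == "cyc",
         tac  = samples$cni == "tac",
         aza  = samples$ap == "aza",
         mmf  = samples$ap == "mmf",
         stop("unknown drug: ", drug))
}

#' Construct and validate a clinical sample table
#'
#' One row per sample, i.e. per (patient, timepoint) pair. The table carries
#' the clinical group, the immunosuppressive regimen as three categorical
#' indicators (prednisolone off/on; calcineurin inhibitor off/cyclosporine/
#' tacrolimus; antiproliferative off/azathioprine/mycophenolate mofetil),
#' optional daily doses in mg/day, and optionally eGFR.
#'
#' Enforced invariants: unique sample ids and (patient, timepoint) pairs;
#' tolerant patients (TOL) and healthy controls (HC) are off all drugs; a dose
#' may only be present when the corresponding indicator is on; doses are
#' non-negative.
#'
#' @param df A data frame with columns `sample_id`, `patient_id`, `timepoint`
#'   (`T1`/`T2`), `group` (`TOL`/`ST`/`CR`/`HC`), `pred` (`off`/`on`),
#'   `cni` (`off`/`cyc`/`tac`), `ap` (`off`/`aza`/`mmf`), and optionally
#'   `dose_pred`, `dose_cyc`, `dose_tac`, `dose_aza`, `dose_mmf`, `egfr`.
#' @return The validated table, classed `"tol_samples"`.
#' @export
#' @examples
#' sample_table(data.frame(
#'   sample_id = c("P1_T1", "P2_T1"), patient_id = c("P1", "P2"),
#'   timepoint = "T1", group = c("TOL", "ST"),
#'   pred = c("off", "on"), cni = c("off", "tac"), ap = c("off", "mmf"),
#'   dose_tac = c(NA, 4), dose_mmf = c(NA, 1000), dose_pred = c(NA, 5)))
sample_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  required <- c("sample_id", "patient_id", "timepoint", "group", "pred", "cni", "ap")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("sample table is missing columns: ", paste(missing_cols, collapse = ", "))
  for (col in DOSE_COLS) if (!col %in% names(df)) df[[col]] <- NA_real_
  df$sample_id <- as.character(df$sample_id)
  df$patient_id <- as.character(df$patient_id)
  df$timepoint <- as.character(df$timepoint)
  df$group <- as.character(df$group)
  df$pred <- as.character(df$pred)
  df$cni <- as.character(df$cni)
  df$ap <- as.character(df$ap)

  check_levels <- function(x, levels, col) {
    bad <- !x %in% levels
    if (any(bad))
      stop("invalid ", col, " value(s): ", paste(unique(x[bad]), collapse = ", "),
           " (allowed: ", paste(levels, collapse = "/"), ")")
  }
  check_levels(df$timepoint, c("T1", "T2"), "timepoint")
  check_levels(df$group, c("TOL", "ST", "CR", "HC"), "group")
  check_levels(df$pred, c("off", "on"), "pred")
  check_levels(df$cni, c("off", "cyc", "tac"), "cni")
  check_levels(df$ap, c("off", "aza", "mmf"), "ap")

  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  key <- paste(df$patient_id, df$timepoint)
  if (anyDuplicated(key))
    stop("duplicated (patient_id, timepoint): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))

  untreated <- df$group %in% c("TOL", "HC")
  bad <- untreated & (df$pred != "off" | df$cni != "off" | df$ap != "off")
  if (any(bad))
    stop("TOL/HC samples must be off all drugs; violated by: ",
         paste(df$sample_id[bad], collapse = ", "))

  for (drug in DRUGS) {
    dose <- df[[paste0("dose_", drug)]]
    if (!is.numeric(dose)) dose <- suppressWarnings(as.numeric(dose))
    df[[paste0("dose_", drug)]] <- dose
    off <- !drug_on(df, drug)
    bad <- off & !is.na(dose)
    if (any(bad))
      stop("dose_", drug, " present while ", drug, " indicator is off: ",
           paste(df$sample_id[bad], collapse = ", "))
    if (any(dose < 0, na.rm = TRUE))
      stop("negative dose_", drug)
  }
  if (!"egfr" %in% names(df)) df$egfr <- NA_real_
  df$egfr <- suppressWarnings(as.numeric(df$egfr))
  rownames(df) <- df$sample_id
  class(df) <- c("tol_samples", "data.frame")
  df
}

#' Read a clinical sample table from CSV/TSV
#'
#' The separator is taken from the file extension (`.tsv`/`.txt` = tab,
#' otherwise comma). All [sample_table()] invariants are enforced.
#'
#' @param path Path to a delimited text file with the columns documented in
#'   [sample_table()].
#' @return A validated `"tol_samples"` table.
#' @export
read_clinical <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  sample_table(df)
}

#' Write a clinical sample table to CSV
#' @param samples A `"tol_samples"` table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_clinical <- function(samples, path) {
  utils::write.csv(as.data.frame(samples), path, row.names = FALSE, na = "")
  invisible(path)
}
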