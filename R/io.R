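#' Read a cohort bundle from disk
#'
#' A cohort bundle is a directory of UTF-8 CSV files with header rows:
#' `admissions.csv` (one row per admission, booleans as 0/1, blank
#' `readmission_gap_days` for index admissions), `labs.csv` (long format:
#' `admission_id, analyte_id, value, sequence`), `deficits.csv`
#' (`admission_id, item_id, value`), and optionally `icd10.csv`
#' (`admission_id, code`). Row order is preserved and every container
#' invariant is enforced on read; violations raise an error naming the row
#' and field.
#'
#' @param path directory containing the bundle.
#' @param panel the active [reference_panel()].
#' @param lenient passed to [fall_cohort()]: drop under-age rows with a
#'   message instead of erroring.
#' @return a validated [fall_cohort()].
#' @export
read_cohort <- function(path, panel = default_panel(), lenient = FALSE) {
  if (!dir.exists(path)) stop("cohort bundle directory not found: ", path)
  need <- file.path(path, c("admissions.csv", "labs.csv", "deficits.csv"))
  absent <- need[!file.exists(need)]
  if (length(absent)) stop("cohort bundle missing file(s): ",
                           paste(basename(absent), collapse = ", "))
  read1 <- function(f) utils::read.csv(f, stringsAsFactors = FALSE,
                                       colClasses = c(admission_id = "character"))
  admissions <- read1(need[1])
  labs <- read1(need[2])
  deficits <- read1(need[3])
  icd_path <- file.path(path, "icd10.csv")
  icd10 <- if (file.exists(icd_path)) read1(icd_path) else NULL
  fall_cohort(admissions, labs, deficits, icd10, panel = panel,
              provenance = paste0("read from ", path), lenient = lenient)
}

#' Write a cohort bundle to disk
#'
#' Inverse of [read_cohort()]: writes `admissions.csv`, `labs.csv`,
#' `deficits.csv` and `icd10.csv` into `path`. Logical columns are written as
#' 0/1 and floating-point values with 17 significant digits, so a
#' write-then-read round trip reproduces the cohort field for field.
#'
#' @param cohort a [fall_cohort()].
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "fall_cohort"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  adm <- cohort$admissions
  for (col in names(adm)) if (is.logical(adm[[col]])) adm[[col]] <- as.integer(adm[[col]])
  write_csv_exact(adm, file.path(path, "admissions.csv"))
  write_csv_exact(cohort$labs, file.path(path, "labs.csv"))
  write_csv_exact(cohort$deficits, file.path(path, "deficits.csv"))
  write_csv_exact(cohort$icd10, file.path(path, "icd10.csv"))
  invisible(path)
}

# CSV writer that round-trips doubles exactly (17 significant digits) and
# writes NA as an empty field
write_csv_exact <- function(df, file) {
  out <- df
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      v <- sprintf("%.17g", out[[col]])
      v[is.na(out[[col]])] <- NA_character_
      out[[col]] <- v
    }
  }
  utils::write.csv(out, file, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(file)
}
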