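#' @title Admission cohort container
#' @description
#' A `fall_cohort` bundles one hospitalization per row together with its
#' long-format laboratory results, clinical deficit items, and ICD-10 codes:
#'
#' * `admissions`: one row per admission — `admission_id`, `age` (years,
#'   >= 60), `sex` (`"male"`/`"female"`), `emergency`, the five STRATIFY items
#'   (`history_of_falls`, `mental_status`, `vision`, `toileting`, `mobility`;
#'   never missing), six medication-category flags (`antihypertensive`,
#'   `antidiabetic`, `antithrombotic`, `sleep`, `antipsychotic`, `nsaid`),
#'   the fall outcome `fell`, and optionally `readmission_gap_days` (whole
#'   days from previous discharge; `NA` for an index admission) and `barthel`.
#' * `labs`: `admission_id`, `analyte_id`, `value`, `sequence`. A missing
#'   result is an absent row, never a sentinel. When an analyte was measured
#'   more than once, only the earliest result (lowest `sequence`, ties broken
#'   by row order) is retained, mirroring first-test-on-admission use.
#' * `deficits`: `admission_id`, `item_id`, `value` with values in
#'   \{0, 0.5, 1\}; a missing item is an absent row.
#' * `icd10`: `admission_id`, `code`.
#'
#' @param admissions,labs,deficits,icd10 data.frames as described above;
#'   `deficits` and `icd10` may be `NULL` (treated as empty).
#' @param panel the active [reference_panel()]; every `analyte_id` in `labs`
#'   must belong to it.
#' @param provenance free-text source description recorded on the object.
#' @param lenient if `TRUE`, rows violating the age >= 60 inclusion rule are
#'   dropped with a message instead of raising an error.
#' @return an object of class `fall_cohort`.
#' @export
fall_cohort <- function(admissions, labs, deficits = NULL, icd10 = NULL,
                        panel = default_panel(), provenance = "",
                        lenient = FALSE) {
  stopifnot(is.data.frame(admissions), inherits(panel, "reference_panel"))
  labs <- empty_if_null(labs, c("admission_id", "analyte_id", "value", "sequence"))
  deficits <- empty_if_null(deficits, c("admission_id", "item_id", "value"))
  icd10 <- empty_if_null(icd10, c("admission_id", "code"))

  req <- c("admission_id", "age", "sex", "emergency", stratify_item_names(),
           med_category_names(), "fell")
  miss <- setdiff(req, names(admissions))
  if (length(miss)) stop("admissions table missing columns: ",
                         paste(miss, collapse = ", "))
  admissions$admission_id <- as.character(admissions$admission_id)
  if (anyDuplicated(admissions$admission_id)) {
    stop("duplicate admission_id in admissions table")
  }
  if (is.null(admissions$readmission_gap_days)) {
    admissions$readmission_gap_days <- NA_integer_
  }
  admissions$readmission_gap_days <- as.integer(admissions$readmission_gap_days)

  bad_sex <- !admissions$sex %in% c("male", "female")
  if (any(bad_sex)) {
    stop("admissions row ", which(bad_sex)[1], " field 'sex': must be 'male' or 'female'")
  }
  for (col in c("emergency", stratify_item_names(), med_category_names(), "fell")) {
    v <- admissions[[col]]
    if (is.numeric(v)) {
      if (!all(v %in% c(0, 1))) {
        stop("admissions field '", col, "': values must be 0/1 or logical")
      }
      v <- v == 1
    }
    if (!is.logical(v)) stop("admissions field '", col, "' must be logical or 0/1")
    admissions[[col]] <- v
  }
  for (col in stratify_item_names()) {
    if (anyNA(admissions[[col]])) {
      stop("admissions field '", col,
           "': STRATIFY items are assessed on every admission and may not be missing")
    }
  }
  admissions$age <- as.integer(admissions$age)
  under <- !is.na(admissions$age) & admissions$age < 60L
  if (anyNA(admissions$age)) stop("admissions field 'age': missing value")
  if (any(under)) {
    if (lenient) {
      message("dropping ", sum(under), " admission(s) under age 60 (inclusion rule)")
      keep <- admissions$admission_id[!under]
      admissions <- admissions[!under, , drop = FALSE]
      labs <- labs[labs$admission_id %in% keep, , drop = FALSE]
      deficits <- deficits[deficits$admission_id %in% keep, , drop = FALSE]
      icd10 <- icd10[icd10$admission_id %in% keep, , drop = FALSE]
    } else {
      stop("admissions row ", which(under)[1],
           " field 'age': inclusion requires age >= 60 (use lenient = TRUE to drop)")
    }
  }

  labs$admission_id <- as.character(labs$admission_id)
  labs$analyte_id <- as.character(labs$analyte_id)
  labs$value <- as.numeric(labs$value)
  if (is.null(labs$sequence)) labs$sequence <- seq_len(nrow(labs))
  labs$sequence <- as.integer(labs$sequence)
  unknown <- !labs$analyte_id %in% panel$analytes$analyte_id
  if (any(unknown)) {
    stop("labs row ", which(unknown)[1], " field 'analyte_id': '",
         labs$analyte_id[which(unknown)[1]], "' not in reference panel '",
         panel$name, "'")
  }
  orphan <- !labs$admission_id %in% admissions$admission_id
  if (any(orphan)) {
    stop("labs row ", which(orphan)[1], " field 'admission_id': unknown admission '",
         labs$admission_id[which(orphan)[1]], "'")
  }
  nonfinite <- !is.finite(labs$value)
  if (any(nonfinite)) {
    stop("labs row ", which(nonfinite)[1], " field 'value': non-finite value")
  }
  labs <- first_result_only(labs)

  deficits$admission_id <- as.character(deficits$admission_id)
  deficits$item_id <- as.character(deficits$item_id)
  deficits$value <- as.numeric(deficits$value)
  bad_val <- !deficits$value %in% c(0, 0.5, 1)
  if (any(bad_val)) {
    stop("deficits row ", which(bad_val)[1], " field 'value': ",
         deficits$value[which(bad_val)[1]],
         " outside the {0, 0.5, 1} deficit domain")
  }
  orphan_d <- !deficits$admission_id %in% admissions$admission_id
  if (any(orphan_d)) {
    stop("deficits row ", which(orphan_d)[1],
         " field 'admission_id': unknown admission")
  }
  dup <- duplicated(deficits[c("admission_id", "item_id")])
  if (any(dup)) stop("deficits row ", which(dup)[1], ": duplicate item for admission")

  icd10$admission_id <- as.character(icd10$admission_id)
  icd10$code <- as.character(icd10$code)

  rownames(admissions) <- rownames(labs) <- rownames(deficits) <- rownames(icd10) <- NULL
  structure(list(admissions = admissions, labs = labs, deficits = deficits,
                 icd10 = icd10, panel = panel,
                 provenance = paste0(provenance,
                                     " [panel: ", panel$name, "]")),
            class = "fall_cohort")
}

stratify_item_names <- function() {
  c("history_of_falls", "mental_status", "vision", "toileting", "mobility")
}

med_category_names <- function() {
  c("antihypertensive", "antidiabetic", "antithrombotic", "sleep",
    "antipsychotic", "nsaid")
}

empty_if_null <- function(df, cols) {
  if (is.null(df)) {
    df <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols),
                        stringsAsFactors = FALSE)
    if ("value" %in% cols) df$value <- numeric(0)
    if ("sequence" %in% cols) df$sequence <- integer(0)
  }
  df
}

# keep only the first result per (admission, analyte): lowest sequence number,
# ties broken by original row order
first_result_only <- function(labs) {
  if (!nrow(labs)) return(labs)
  ord <- order(labs$admission_id, labs$analyte_id, labs$sequence,
               seq_len(nrow(labs)))
  labs <- labs[ord, , drop = FALSE]
  keep <- !duplicated(labs[c("admission_id", "analyte_id")])
  labs <- labs[keep, , drop = FALSE]
  rownames(labs) <- NULL
  labs
}

#' @export
print.fall_cohort <- function(x, ...) {
  n <- nrow(x$admissions)
  cat("fall_cohort:", n, "admissions |", nrow(x$labs), "lab results |",
      nrow(x$deficits), "deficit items\n")
  if (n) {
    cat(sprintf("  age %d-%d, %.1f%% male, %.1f%% fell\n",
                min(x$admissions$age), max(x$admissions$age),
                100 * mean(x$admissions$sex == "male"),
                100 * mean(x$admissions$fell)))
  }
  cat(" ", x$provenance, "\n")
  invisible(x)
}

#' Number of distinct analytes measured per admission
#'
#' @param cohort a [fall_cohort()].
#' @return integer vector aligned with `cohort$admissions` rows.
#' @keywords internal
measured_counts <- function(cohort) {
  ids <- cohort$admissions$admission_id
  cnt <- integer(length(ids))
  if (nrow(cohort$labs)) {
    tab <- table(factor(cohort$labs$admission_id, levels = ids))
    cnt <- as.integer(tab)
  }
  cnt
}

#' Apply the study exclusion rules
#'
#' Removes (a) readmissions within 30 days of a previous discharge
#' (`readmission_gap_days <= 30`; an `NA` gap marks an index admission) and
#' (b) admissions ineligible for FI-lab because fewer than 70% of panel
#' analytes were measured. Returns the retained cohort together with an
#' exclusion-flow tally whose counts (`a_only`, `b_only`, `both`, `included`)
#' always sum to the raw record count.
#'
#' @param raw a [fall_cohort()].
#' @return list with elements `included` (a `fall_cohort`) and `flow`
#'   (class `exclusion_flow`).
#' @export
apply_exclusions <- function(raw) {
  stopifnot(inherits(raw, "fall_cohort"))
  adm <- raw$admissions
  gap <- adm$readmission_gap_days
  a <- !is.na(gap) & gap <= 30L
  ratio <- measured_counts(raw) / raw$panel$size
  b <- ratio < 0.7
  flow <- structure(list(raw_n = nrow(adm),
                         a_only = sum(a & !b),
                         b_only = sum(!a & b),
                         both = sum(a & b),
                         included = sum(!a & !b)),
                    class = "exclusion_flow")
  keep_ids <- adm$admission_id[!a & !b]
  list(included = subset_cohort(raw, keep_ids), flow = flow)
}

#' @export
print.exclusion_flow <- function(x, ...) {
  cat("Exclusion flow:", x$raw_n, "raw admissions\n")
  cat("  readmission <= 30 days only:", x$a_only, "\n")
  cat("  insufficient labs (<70% measured) only:", x$b_only, "\n")
  cat("  both:", x$both, "\n")
  cat("  included:", x$included, "\n")
  invisible(x)
}

subset_cohort <- function(cohort, keep_ids) {
  out <- cohort
  out$admissions <- cohort$admissions[cohort$admissions$admission_id %in% keep_ids, ,
                                      drop = FALSE]
  out$labs <- cohort$labs[cohort$labs$admission_id %in% keep_ids, , drop = FALSE]
  out$deficits <- cohort$deficits[cohort$deficits$admission_id %in% keep_ids, ,
                                  drop = FALSE]
  out$icd10 <- cohort$icd10[cohort$icd10$admission_id %in% keep_ids, , drop = FALSE]
  rownames(out$admissions) <- rownames(out$labs) <- rownames(out$deficits) <-
    rownames(out$icd10) <- NULL
  out
}
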