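#' Flag laboratory values outside their reference interval
#'
#' A result counts as one FI-lab deficit when its value lies strictly outside
#' the panel's reference interval for that analyte (sex-specific limits where
#' declared). Values equal to a limit are normal: the interval is inclusive.
#'
#' @param value numeric vector of results (finite).
#' @param analyte_id character vector of panel analyte codes (recycled with
#'   `value`).
#' @param sex `"male"`/`"female"`, scalar or vector.
#' @param panel a [reference_panel()].
#' @return integer vector of 0/1 deficit flags.
#' @export
flag_abnormal <- function(value, analyte_id, sex, panel = default_panel()) {
  if (any(!is.finite(value))) stop("non-finite laboratory value")
  idx <- match(analyte_id, panel$analytes$analyte_id)
  if (anyNA(idx)) {
    stop("analyte not in panel: ", analyte_id[which(is.na(idx))[1]])
  }
  n <- max(length(value), length(idx), length(sex))
  value <- rep_len(value, n); idx <- rep_len(idx, n); sex <- rep_len(sex, n)
  if (any(!sex %in% c("male", "female"))) stop("sex must be 'male' or 'female'")
  a <- panel$analytes
  lo <- ifelse(sex == "male", effective_limit(a, "lower", "male")[idx],
               effective_limit(a, "lower", "female")[idx])
  hi <- ifelse(sex == "male", effective_limit(a, "upper", "male")[idx],
               effective_limit(a, "upper", "female")[idx])
  as.integer((!is.na(lo) & value < lo) | (!is.na(hi) & value > hi))
}

#' Laboratory frailty index for one admission
#'
#' FI-lab is the number of abnormal results divided by the number of tests
#' performed. The measured ratio is the number of tests performed divided by
#' the panel size (35 by default). An admission is eligible for FI-lab only
#' when the measured ratio is at least 0.7, compared as an exact rational
#' (25/35 passes, 24/35 fails); otherwise the score is `NA`.
#'
#' @param value,analyte_id one admission's first-on-admission results, long
#'   format.
#' @param sex `"male"` or `"female"`.
#' @param panel a [reference_panel()].
#' @return list with `fi_lab` (`NA` when ineligible), `measured_ratio`,
#'   `measured`, `abnormal`.
#' @export
fi_lab_score <- function(value, analyte_id, sex, panel = default_panel()) {
  if (anyDuplicated(analyte_id)) {
    stop("duplicate analyte results; apply the first-result rule upstream")
  }
  measured <- length(value)
  ratio <- measured / panel$size
  if (measured * 10 < panel$size * 7) {   # exact measured/size < 0.7
    return(list(fi_lab = NA_real_, measured_ratio = ratio,
                measured = measured, abnormal = NA_integer_))
  }
  abnormal <- sum(flag_abnormal(value, analyte_id, sex, panel))
  list(fi_lab = abnormal / measured, measured_ratio = ratio,
       measured = measured, abnormal = abnormal)
}

#' Band an FI-lab score at the conventional cut-off points
#'
#' Bands follow the previously reported cut-offs: `low` below 0.25, `mid`
#' for 0.25 through 0.4 inclusive, `high` above 0.4. At the 0.4 cut-off the
#' band agrees with [binarize_fi_lab()]: `high` exactly when the binary
#' indicator is 1.
#'
#' @param score numeric vector in \[0, 1\].
#' @return factor with levels `low`, `mid`, `high`.
#' @export
band_fi_lab <- function(score) {
  ok <- is.na(score) | (score >= 0 & score <= 1)
  if (!all(ok)) stop("FI-lab score outside [0, 1]")
  bands <- ifelse(score < 0.25, "low", ifelse(score <= 0.4, "mid", "high"))
  factor(bands, levels = c("low", "mid", "high"))
}

#' Binary FI-lab indicator
#'
#' Dichotomizes FI-lab at a cut-off, scoring 1 only for values strictly above
#' it (a score equal to the cut-off is 0, i.e. the split is `<= 0.4` versus
#' `> 0.4` at the default). The 0.345 alternative cut-off used in sensitivity
#' analyses is supported through the `cutoff` argument.
#'
#' @param score numeric vector in \[0, 1\].
#' @param cutoff decision threshold, default 0.4.
#' @return integer vector of 0/1 (NA propagated).
#' @export
binarize_fi_lab <- function(score, cutoff = 0.4) {
  ok <- is.na(score) | (score >= 0 & score <= 1)
  if (!all(ok)) stop("FI-lab score outside [0, 1]")
  as.integer(score > cutoff)
}

#' Clinical frailty index for one admission
#'
#' The clinical (non-laboratory) frailty index is the sum of deficit values
#' (each 0, 0.5 or 1) divided by the number of items assessed. It is computed
#' only when at least 80% of the item schema (40 items by default) is
#' non-missing; otherwise `NA`.
#'
#' @param values numeric vector of item values with `NA` for missing items;
#'   at most `n_items` entries.
#' @param n_items size of the item schema (default 40).
#' @return the index in \[0, 1\], or `NA` when ineligible.
#' @export
fi_clinical_score <- function(values, n_items = 40L) {
  if (length(values) > n_items) stop("more deficit values than schema items")
  ok <- is.na(values) | values %in% c(0, 0.5, 1)
  if (!all(ok)) stop("deficit values must lie in {0, 0.5, 1}")
  observed <- sum(!is.na(values))
  if (observed * 10 < n_items * 8) return(NA_real_)  # exact observed/n < 0.8
  sum(values, na.rm = TRUE) / observed
}

#' Modified STRATIFY score
#'
#' Sum of the five binary STRATIFY items (history of falls, mental status,
#' vision, toileting, mobility), each worth one point, range 0-5. The mental
#' status item here follows the modified criterion covering confusion,
#' disorientation, and agitation rather than agitation alone.
#'
#' @param items named logical vector (or 0/1) with entries
#'   `history_of_falls`, `mental_status`, `vision`, `toileting`, `mobility`.
#' @return integer 0-5.
#' @export
stratify_score <- function(items) {
  need <- stratify_item_names()
  if (!all(need %in% names(items))) {
    stop("missing STRATIFY item(s): ",
         paste(setdiff(need, names(items)), collapse = ", "))
  }
  v <- items[need]
  if (anyNA(v)) stop("STRATIFY items may not be missing")
  sum(as.integer(as.logical(v)))
}

#' STRATIFY extended with a binary FI-lab item
#'
#' The six-item score adds one point to STRATIFY when FI-lab exceeds 0.4
#' (range 0-6). An FI-lab-ineligible admission propagates `NA`.
#'
#' @param stratify integer STRATIFY score(s), 0-5.
#' @param fi_lab FI-lab score(s); `NA` marks ineligibility.
#' @param cutoff FI-lab threshold for the sixth item, default 0.4.
#' @return integer 0-6 (NA where FI-lab is ineligible).
#' @export
stratify_plus_filab <- function(stratify, fi_lab, cutoff = 0.4) {
  stopifnot(all(stratify %in% 0:5))
  as.integer(stratify + binarize_fi_lab(fi_lab, cutoff))
}

#' Polypharmacy score
#'
#' Count of six medication categories in use on admission (antihypertensives,
#' antidiabetics, antithrombotics, sleep drugs, antipsychotics, NSAIDs),
#' range 0-6.
#'
#' @param flags named logical vector (or 0/1) with entries
#'   `antihypertensive`, `antidiabetic`, `antithrombotic`, `sleep`,
#'   `antipsychotic`, `nsaid`.
#' @return integer 0-6.
#' @export
polypharmacy_score <- function(flags) {
  need <- med_category_names()
  if (!all(need %in% names(flags))) {
    stop("missing medication category flag(s): ",
         paste(setdiff(need, names(flags)), collapse = ", "))
  }
  v <- flags[need]
  if (anyNA(v)) stop("medication category flags may not be missing")
  sum(as.integer(as.logical(v)))
}

#' Derive all per-admission scores for a cohort
#'
#' Computes, for every admission: the measured ratio, FI-lab (with band and
#' binary forms), the clinical frailty index, STRATIFY, STRATIFY including
#' the binary FI-lab item, the polypharmacy score, and the Charlson
#' Comorbidity Index, joined on `admission_id`. Missing (`NA`) FI-lab or
#' FI-clinical marks eligibility failure, never an imputed value.
#'
#' @param cohort a [fall_cohort()].
#' @param n_fic_items clinical frailty-index schema size (default 40).
#' @param cci_map condition map for the Charlson index, default
#'   [default_cci_map()].
#' @return data.frame with one row per admission: `admission_id`, `age`,
#'   `sex`, `emergency`, `fell`, `measured_ratio`, `fi_lab`, `fi_lab_band`,
#'   `fi_lab_binary`, `fi_clinical`, `stratify`, `stratify_filab`,
#'   `polypharmacy`, `cci` (plus `barthel` when present on the cohort).
#' @export
compute_scores <- function(cohort, n_fic_items = 40L, cci_map = default_cci_map()) {
  stopifnot(inherits(cohort, "fall_cohort"))
  adm <- cohort$admissions
  ids <- adm$admission_id
  pos <- stats::setNames(seq_along(ids), ids)

  # FI-lab, vectorized over the long lab table
  measured <- measured_counts(cohort)
  abnormal <- integer(length(ids))
  if (nrow(cohort$labs)) {
    li <- pos[cohort$labs$admission_id]
    flags <- flag_abnormal(cohort$labs$value, cohort$labs$analyte_id,
                           adm$sex[li], cohort$panel)
    ab <- rowsum(flags, group = li)
    abnormal[as.integer(rownames(ab))] <- ab[, 1]
  }
  measured_ratio <- measured / cohort$panel$size
  eligible <- measured * 10 >= cohort$panel$size * 7
  fi_lab <- ifelse(eligible, abnormal / pmax(measured, 1L), NA_real_)

  # FI-clinical from the long deficit table
  n_obs <- integer(length(ids))
  v_sum <- numeric(length(ids))
  if (nrow(cohort$deficits)) {
    di <- pos[cohort$deficits$admission_id]
    tab <- table(factor(di, levels = seq_along(ids)))
    n_obs <- as.integer(tab)
    vs <- rowsum(cohort$deficits$value, group = di)
    v_sum[as.integer(rownames(vs))] <- vs[, 1]
  }
  fic_eligible <- n_obs * 10 >= n_fic_items * 8
  fi_clinical <- ifelse(fic_eligible, v_sum / pmax(n_obs, 1L), NA_real_)

  stratify <- rowSums(sapply(stratify_item_names(),
                             function(cn) as.integer(adm[[cn]])))
  polypharmacy <- rowSums(sapply(med_category_names(),
                                 function(cn) as.integer(adm[[cn]])))

  codes_by_adm <- split(cohort$icd10$code,
                        factor(cohort$icd10$admission_id, levels = ids))
  cci <- vapply(codes_by_adm, cci_score, integer(1), map = cci_map)

  out <- data.frame(
    admission_id = ids,
    age = adm$age,
    sex = adm$sex,
    emergency = adm$emergency,
    fell = adm$fell,
    measured_ratio = measured_ratio,
    fi_lab = fi_lab,
    fi_lab_binary = binarize_fi_lab(fi_lab),
    fi_clinical = fi_clinical,
    stratify = as.integer(stratify),
    stratify_filab = ifelse(is.na(fi_lab), NA_integer_,
                            as.integer(stratify + binarize_fi_lab(fi_lab))),
    polypharmacy = as.integer(polypharmacy),
    cci = as.integer(cci),
    stringsAsFactors = FALSE
  )
  out$fi_lab_band <- band_fi_lab(out$fi_lab)
  if (!is.null(adm$barthel)) out$barthel <- adm$barthel
  rownames(out) <- NULL
  out
}
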