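#' Default ICD-10 condition map for the Charlson Comorbidity Index
#'
#' The Quan et al. ICD-10 coding of the 17 Charlson conditions with the
#' original Charlson weights, shipped as an editable CSV
#' (`system.file("extdata", "cci_icd10_quan.csv", package = "frailtyfalls")`).
#' Each condition lists its code prefixes (dots removed) and, for
#' hierarchical pairs (diabetes with/without complication, mild versus
#' moderate/severe liver disease, malignancy versus metastatic solid tumour),
#' the condition that supersedes it.
#'
#' @param path alternative mapping CSV with columns `condition`, `weight`,
#'   `supersedes`, `prefixes` (semicolon-separated).
#' @return a `cci_map` object.
#' @export
default_cci_map <- function(path = system.file("extdata", "cci_icd10_quan.csv",
                                               package = "frailtyfalls")) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("condition", "weight", "supersedes", "prefixes") %in% names(raw)))
  prefixes <- strsplit(raw$prefixes, ";", fixed = TRUE)
  structure(list(condition = raw$condition,
                 weight = as.integer(raw$weight),
                 supersedes = raw$supersedes,
                 prefixes = lapply(prefixes, toupper)),
            class = "cci_map")
}

#' Charlson Comorbidity Index from ICD-10 codes
#'
#' A condition is present when any code matches one of its prefixes (codes
#' are upper-cased and dots removed before matching; unrecognized codes are
#' ignored). Hierarchical condition pairs count once at the higher weight:
#' for example, codes hitting both a primary malignancy and a metastatic
#' solid tumour contribute only the metastatic weight. The score is the sum
#' of the weights of the retained conditions.
#'
#' @param codes character vector of ICD-10 codes for one admission (may be
#'   empty).
#' @param map a condition map from [default_cci_map()].
#' @return integer score, 0 or more.
#' @export
cci_score <- function(codes, map = default_cci_map()) {
  stopifnot(inherits(map, "cci_map"))
  if (!length(codes)) return(0L)
  codes <- toupper(gsub("[. ]", "", as.character(codes)))
  hit <- vapply(map$prefixes, function(pf) {
    any(vapply(pf, function(p) any(startsWith(codes, p)), logical(1)))
  }, logical(1))
  # hierarchy: drop a condition when its superseding condition is also hit
  sup_idx <- match(map$supersedes, map$condition)
  drop <- !is.na(sup_idx) & hit & hit[ifelse(is.na(sup_idx), 1L, sup_idx)]
  hit[drop] <- FALSE
  sum(map$weight[hit])
}
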