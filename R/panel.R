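#' Reference panel for the laboratory frailty index
#'
#' A reference panel lists the laboratory analytes that enter FI-lab together
#' with their reference intervals. A value strictly outside its interval counts
#' as one deficit; a value equal to a limit is normal. Intervals may be
#' sex-specific (for example haemoglobin or creatinine), in which case the
#' per-sex limits override the shared ones for that analyte.
#'
#' @param analytes data.frame with columns `analyte_id`, `units`, `lower`,
#'   `upper`, and optionally `lower_male`, `upper_male`, `lower_female`,
#'   `upper_female`. Missing limits are `NA`; each analyte must carry at least
#'   one usable limit for each sex, and `lower < upper` whenever both are
#'   present.
#' @param name short label identifying the panel version.
#'
#' @return an object of class `reference_panel`.
#' @seealso [default_panel()], [read_reference_panel()]
#' @export
reference_panel <- function(analytes, name = "custom") {
  stopifnot(is.data.frame(analytes))
  req <- c("analyte_id", "units", "lower", "upper")
  missing_cols <- setdiff(req, names(analytes))
  if (length(missing_cols)) {
    stop("reference panel is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  for (col in c("lower_male", "upper_male", "lower_female", "upper_female")) {
    if (is.null(analytes[[col]])) analytes[[col]] <- NA_real_
  }
  analytes$analyte_id <- as.character(analytes$analyte_id)
  if (anyDuplicated(analytes$analyte_id)) {
    stop("duplicate analyte_id in reference panel")
  }
  for (sx in c("male", "female")) {
    lo <- effective_limit(analytes, "lower", sx)
    hi <- effective_limit(analytes, "upper", sx)
    no_limit <- is.na(lo) & is.na(hi)
    if (any(no_limit)) {
      stop("analytes without any reference limit: ",
           paste(analytes$analyte_id[no_limit], collapse = ", "))
    }
    bad <- !is.na(lo) & !is.na(hi) & lo >= hi
    if (any(bad)) {
      stop("lower limit must be below upper limit for: ",
           paste(analytes$analyte_id[bad], collapse = ", "))
    }
  }
  rownames(analytes) <- NULL
  structure(list(analytes = analytes, name = name, size = nrow(analytes)),
            class = "reference_panel")
}

# sex-resolved limit vector: per-sex limit where declared, else the shared one
effective_limit <- function(analytes, side, sex) {
  shared <- analytes[[side]]
  specific <- analytes[[paste(side, sex, sep = "_")]]
  ifelse(is.na(specific), shared, specific)
}

#' Read a reference panel from a YAML or JSON file
#'
#' The file holds a `name` and a `panel` list; each entry gives `analyte_id`,
#' `units`, and either shared `lower`/`upper` limits or per-sex
#' `male:`/`female:` blocks.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` panel file.
#' @return a [reference_panel()] object.
#' @export
read_reference_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  entries <- raw$panel
  if (is.null(entries)) stop("panel file has no 'panel' entry: ", path)
  num_or_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  rows <- lapply(entries, function(e) {
    data.frame(
      analyte_id = as.character(e$analyte_id),
      units = as.character(e$units %||% ""),
      lower = num_or_na(e$lower),
      upper = num_or_na(e$upper),
      lower_male = num_or_na(e$male$lower),
      upper_male = num_or_na(e$male$upper),
      lower_female = num_or_na(e$female$lower),
      upper_female = num_or_na(e$female$upper),
      stringsAsFactors = FALSE
    )
  })
  reference_panel(do.call(rbind, rows), name = raw$name %||% basename(path))
}

#' The default 35-analyte FI-lab panel
#'
#' A common-blood-count plus chemistry panel of 35 routinely measured analytes
#' with textbook adult reference intervals, shipped as editable YAML
#' (`system.file("extdata", "panel_default.yaml", package = "frailtyfalls")`).
#' Sites should substitute their own laboratory's intervals; the panel is
#' configuration, not code.
#'
#' @return a [reference_panel()] with 35 analytes.
#' @export
default_panel <- function() {
  p <- read_reference_panel(
    system.file("extdata", "panel_default.yaml", package = "frailtyfalls"))
  stopifnot(p$size == 35L)
  p
}

#' @export
print.reference_panel <- function(x, ...) {
  cat("Reference panel '", x$name, "': ", x$size, " analytes\n", sep = "")
  n_sex <- sum(!is.na(x$analytes$lower_male) | !is.na(x$analytes$upper_male) |
                 !is.na(x$analytes$lower_female) | !is.na(x$analytes$upper_female))
  cat("  sex-specific intervals for", n_sex, "analytes\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
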