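#' Study configuration
#'
#' Bundles everything one end-to-end run needs: the input (a [sim_config()]
#' to simulate, or a path to a cohort bundle for [read_cohort()]), the model
#' subset, the ordered model comparisons (reference first; default: `m1`
#' against each of `m2` ... `m6`), the bootstrap size and seed for internal
#' validation, and optional subgroup and sensitivity switches.
#'
#' @param input a [sim_config()] or a directory path.
#' @param panel a [reference_panel()] (or path to one); default panel if
#'   `NULL`.
#' @param models model ids to fit.
#' @param comparisons list of `c(reference, new)` model-id pairs.
#' @param B bootstrap resamples for validation.
#' @param seed integer seed governing simulation and validation.
#' @param subgroups run age- and sex-stratified suites.
#' @param adjust sensitivity covariates appended to the models
#'   (`"polypharmacy"`, `"cci"`), or `NULL`.
#' @param cutoff_scan also search the Youden-optimal FI-lab cutpoint.
#' @param validate_models model ids to internally validate (default: all
#'   fitted models).
#' @return object of class `study_config`.
#' @export
study_config <- function(input, panel = NULL, models = paste0("m", 1:6),
                         comparisons = lapply(paste0("m", 2:6),
                                              function(m) c("m1", m)),
                         B = 1000L, seed, subgroups = FALSE, adjust = NULL,
                         cutoff_scan = TRUE, validate_models = NULL) {
  if (missing(seed) || is.null(seed)) stop("study_config requires an explicit seed")
  for (cmp in comparisons) {
    if (length(cmp) != 2L || !all(cmp %in% models)) {
      stop("each comparison must be a (reference, new) pair drawn from 'models'")
    }
  }
  structure(list(input = input, panel = panel, models = models,
                 comparisons = comparisons, B = as.integer(B),
                 seed = as.integer(seed), subgroups = isTRUE(subgroups),
                 adjust = adjust, cutoff_scan = isTRUE(cutoff_scan),
                 validate_models = validate_models),
            class = "study_config")
}

#' Run the full analysis pipeline
#'
#' Simulate or ingest a cohort, apply the exclusion rules, derive all scores,
#' produce descriptive and correlation tables, fit the model suite, compare
#' models by DeLong/NRI/IDI, internally validate, and (optionally) run
#' subgroup suites and the FI-lab cutpoint scan. When `out_dir` is given the
#' report bundle is written as CSV files plus a JSON run manifest and a plain
#' text log; two runs with the same configuration and seed produce
#' byte-identical bundles. NRI and IDI are reported as `NA` for comparisons
#' whose new model does not contain every score of the reference model
#' (reclassification against a reference score the new model dropped is not
#' meaningful), mirroring the `n/a` convention for the FI-lab + FI-clinical
#' model versus STRATIFY.
#'
#' @param config a [study_config()].
#' @param out_dir output directory for the report bundle, or `NULL` to only
#'   return the results.
#' @return (invisibly) a list: `cohort`, `flow`, `scores`, `descriptives`,
#'   `correlations`, `suite`, `comparisons`, `validation`, `subgroups`,
#'   `cutoff`, `manifest`, `partial`, `diagnostics`.
#' @export
run_study <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  panel <- config$panel
  if (is.null(panel)) panel <- default_panel()
  if (is.character(panel)) panel <- read_reference_panel(panel)
  log_lines <- character(0)
  diagnostics <- list()
  partial <- FALSE
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      diagnostics[[name]] <<- conditionMessage(e)
      partial <<- TRUE
      say("stage %s FAILED: %s", name, conditionMessage(e))
      NULL
    })
  }

  raw <- stage("input", {
    if (inherits(config$input, "sim_config")) {
      say("simulating cohort: n = %d, seed = %d", config$input$n, config$input$seed)
      simulate_cohort(config$input, panel = panel)
    } else {
      say("reading cohort bundle from %s", config$input)
      read_cohort(config$input, panel = panel)
    }
  })
  if (is.null(raw)) return(finish_study(NULL, log_lines, diagnostics, TRUE,
                                        config, out_dir))

  excl <- apply_exclusions(raw)
  flow <- excl$flow
  say("exclusion flow: raw %d | readmission-only %d | labs-only %d | both %d | included %d",
      flow$raw_n, flow$a_only, flow$b_only, flow$both, flow$included)

  scores <- stage("scores", compute_scores(excl$included))
  res <- list(cohort = excl$included, flow = flow, scores = scores)
  if (is.null(scores)) return(finish_study(res, log_lines, diagnostics, TRUE,
                                           config, out_dir))
  say("fall rate: %d / %d = %.1f%%", sum(scores$fell), nrow(scores),
      100 * sum(scores$fell) / nrow(scores))

  res$descriptives <- stage("descriptives", descriptives(scores))
  res$correlations <- stage("correlations", score_correlations(scores))

  # analysis set: complete cases for the union of requested model terms
  terms_needed <- unique(unlist(lapply(config$models, model_terms,
                                       adjust = config$adjust)))
  analysis <- scores[stats::complete.cases(scores[, c("fell", terms_needed)]), ,
                     drop = FALSE]
  if (nrow(analysis) < nrow(scores)) {
    say("analysis set: %d of %d admissions complete for all model terms",
        nrow(analysis), nrow(scores))
  }

  res$suite <- stage("models", run_model_suite(analysis, models = config$models,
                                               adjust = config$adjust))
  if (!is.null(res$suite)) {
    say("fitted %d models; EPV (m2) = %s", length(res$suite$fits),
        if (is.na(res$suite$epv)) "n/a" else sprintf("%.1f", res$suite$epv))
  }

  res$comparisons <- stage("comparisons",
                           compare_suite(res$suite, analysis$fell,
                                         config$comparisons))

  vmods <- config$validate_models
  if (is.null(vmods)) vmods <- names(res$suite$fits)
  res$validation <- stage("validation", {
    reports <- lapply(vmods, function(mid) {
      validate_model(analysis, model = mid, B = config$B,
                     seed = config$seed, adjust = config$adjust)
    })
    names(reports) <- vmods
    reports
  })

  if (config$subgroups) {
    res$subgroups <- stage("subgroups", {
      list(age = subgroup_suite(analysis, by = "age", models = config$models,
                                univariate = FALSE),
           sex = subgroup_suite(analysis, by = "sex", models = config$models,
                                univariate = FALSE))
    })
  }
  if (config$cutoff_scan) {
    res$cutoff <- stage("cutoff_scan",
                        optimal_cutoff(analysis$fi_lab, analysis$fell))
    if (!is.null(res$cutoff)) {
      say("Youden-optimal FI-lab cutpoint: %.4g (J = %.3f)",
          res$cutoff$cutoff, res$cutoff$youden)
    }
  }
  finish_study(res, log_lines, diagnostics, partial, config, out_dir)
}

#' Compare fitted models by DeLong AUROC, NRI and IDI
#'
#' @param suite a [run_model_suite()] result.
#' @param fell outcome vector aligned with the suite's analysis rows.
#' @param comparisons list of `c(reference, new)` model-id pairs.
#' @return data.frame, one row per comparison, with the reference and new
#'   AUCs and CIs, the DeLong p, and NRI/IDI with CIs and p-values (`NA`
#'   where the new model omits a reference score).
#' @export
compare_suite <- function(suite, fell, comparisons) {
  rows <- lapply(comparisons, function(cmp) {
    ref <- suite$fits[[cmp[1]]]; new <- suite$fits[[cmp[2]]]
    if (is.null(ref) || is.null(new)) {
      stop("comparison (", cmp[1], ", ", cmp[2], "): model not fitted")
    }
    dl <- delong_test(new$fitted, ref$fitted, fell)
    # reclassification is only meaningful when the new model retains every
    # score of the reference model; the six-item STRATIFY-including-FI-lab
    # term subsumes plain STRATIFY
    covers <- function(term) {
      term %in% new$predictors ||
        (term == "stratify" && "stratify_filab" %in% new$predictors)
    }
    reclass_ok <- all(vapply(ref$predictors, covers, logical(1)))
    if (reclass_ok) {
      nr <- continuous_nri(ref$fitted, new$fitted, fell)
      id <- idi(ref$fitted, new$fitted, fell)
      nri_cells <- c(nr$estimate, nr$ci, nr$p)
      idi_cells <- c(id$estimate, id$ci, id$p)
    } else {
      nri_cells <- idi_cells <- rep(NA_real_, 4)
    }
    data.frame(reference = cmp[1], model = cmp[2],
               auc_ref = dl$auc_b, auc_ref_lo = dl$ci_b[1], auc_ref_hi = dl$ci_b[2],
               auc_new = dl$auc_a, auc_new_lo = dl$ci_a[1], auc_new_hi = dl$ci_a[2],
               delta_auc = dl$auc_a - dl$auc_b, delong_p = dl$p,
               nri = nri_cells[1], nri_lo = nri_cells[2], nri_hi = nri_cells[3],
               nri_p = nri_cells[4],
               idi = idi_cells[1], idi_lo = idi_cells[2], idi_hi = idi_cells[3],
               idi_p = idi_cells[4],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Descriptive summary of a scored cohort
#'
#' Mean ± SD for symmetric continuous variables, median (IQR,
#' linear-interpolation type-7 quantiles) for skewed ones (both for Barthel
#' and STRATIFY, whose dual reporting is conventional), and counts (%) for
#' binary variables, including each STRATIFY item and the FI-lab band
#' breakdown.
#'
#' @param scores data.frame from [compute_scores()].
#' @return data.frame with `variable`, `stat`, `value`, `value2`, `label`.
#' @export
descriptives <- function(scores) {
  rows <- list()
  add <- function(variable, stat, value, value2 = NA_real_, label = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, stat = stat, value = value, value2 = value2,
      label = label, stringsAsFactors = FALSE)
  }
  n <- nrow(scores)
  add("participants", "n", n, label = sprintf("%d (100.0)", n))
  mean_sd <- function(v, name) {
    add(name, "mean_sd", mean(v, na.rm = TRUE), stats::sd(v, na.rm = TRUE),
        sprintf("%.2f +/- %.2f", mean(v, na.rm = TRUE), stats::sd(v, na.rm = TRUE)))
  }
  med_iqr <- function(v, name) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE, type = 7)
    add(name, "median_iqr", q[2], q[3] - q[1],
        sprintf("%g (%g-%g)", q[2], q[1], q[3]))
  }
  n_pct <- function(x, name) {
    k <- sum(x, na.rm = TRUE)
    add(name, "n_pct", k, 100 * k / n, sprintf("%d (%.1f)", k, 100 * k / n))
  }
  mean_sd(scores$age, "age")
  n_pct(scores$sex == "male", "male_sex")
  n_pct(scores$emergency, "emergency")
  if (!is.null(scores$barthel)) {
    med_iqr(scores$barthel, "barthel")
    mean_sd(scores$barthel, "barthel")
  }
  med_iqr(scores$cci, "cci")
  med_iqr(scores$polypharmacy, "polypharmacy")
  med_iqr(scores$stratify, "stratify")
  mean_sd(scores$stratify, "stratify")
  mean_sd(scores$fi_lab, "fi_lab")
  mean_sd(scores$measured_ratio, "measured_ratio")
  mean_sd(scores$fi_clinical, "fi_clinical")
  for (band in levels(scores$fi_lab_band)) {
    n_pct(scores$fi_lab_band == band, paste0("fi_lab_band_", band))
  }
  n_pct(scores$fell, "in_hospital_falls")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Spearman rank correlations among the fall-risk scores
#'
#' Tie-corrected Spearman correlations (Pearson correlation of midranks)
#' with t-approximation p-values, for the conventional pairs: FI-lab against
#' age, Barthel (when present), CCI, STRATIFY and FI-clinical, plus STRATIFY
#' against FI-clinical.
#'
#' @param scores data.frame from [compute_scores()].
#' @return data.frame `var1`, `var2`, `rho`, `n`, `p`.
#' @export
score_correlations <- function(scores) {
  pairs <- list(c("fi_lab", "age"), c("fi_lab", "cci"),
                c("fi_lab", "stratify"), c("fi_lab", "fi_clinical"),
                c("stratify", "fi_clinical"))
  if (!is.null(scores$barthel)) {
    pairs <- append(pairs, list(c("fi_lab", "barthel")), after = 1)
  }
  rows <- lapply(pairs, function(pr) {
    sp <- spearman_rho(scores[[pr[1]]], scores[[pr[2]]])
    data.frame(var1 = pr[1], var2 = pr[2], rho = sp$rho, n = sp$n, p = sp$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Spearman correlation with t-approximation p-value
#'
#' Pearson correlation of midranks (the tie-corrected Spearman coefficient)
#' with the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on
#' `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors; incomplete pairs are dropped.
#' @return list `rho`, `n`, `p`.
#' @export
spearman_rho <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) return(list(rho = NA_real_, n = n, p = NA_real_))
  rho <- stats::cor(rank(x, ties.method = "average"),
                    rank(y, ties.method = "average"))
  if (is.na(rho) || abs(rho) >= 1) {
    return(list(rho = rho, n = n, p = if (is.na(rho)) NA_real_ else 0))
  }
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, n = n, p = 2 * stats::pt(-abs(tt), df = n - 2))
}

finish_study <- function(res, log_lines, diagnostics, partial, config, out_dir) {
  res$partial <- partial
  res$diagnostics <- diagnostics
  res$log <- log_lines
  res$manifest <- study_manifest(config)
  if (!is.null(out_dir)) write_study_bundle(res, out_dir)
  if (partial) {
    warning("study run is partial; see $diagnostics")
  }
  invisible(res)
}

study_manifest <- function(config) {
  cfg <- unclass(config)
  cfg$input <- if (inherits(config$input, "sim_config")) {
    unclass(config$input)
  } else {
    as.character(config$input)
  }
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, null = "null")
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  hash <- unname(tools::md5sum(tmp)); unlink(tmp)
  list(config = cfg, config_md5 = hash, seed = config$seed,
       package = "frailtyfalls",
       version = as.character(utils::packageVersion("frailtyfalls")))
}

write_study_bundle <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    if (!is.null(df)) write_csv_exact(df, file.path(out_dir, name))
  }
  if (!is.null(res$flow)) {
    wr(data.frame(stage = c("raw", "readmission_only", "insufficient_labs_only",
                            "both", "included"),
                  n = c(res$flow$raw_n, res$flow$a_only, res$flow$b_only,
                        res$flow$both, res$flow$included)),
       "exclusion_flow.csv")
  }
  wr(res$descriptives, "table1_descriptives.csv")
  wr(res$correlations, "correlations.csv")
  if (!is.null(res$suite)) {
    or_rows <- lapply(names(res$suite$fits), function(mid) {
      tab <- odds_ratios(res$suite$fits[[mid]])
      tab$model <- mid
      tab$or_fmt <- sprintf("%.2f (%.2f-%.2f)", tab$or, tab$ci_low, tab$ci_high)
      tab[, c("model", "term", "unit", "or", "ci_low", "ci_high", "p", "or_fmt")]
    })
    uni_rows <- lapply(names(res$suite$uni), function(tm) {
      tab <- odds_ratios(res$suite$uni[[tm]])
      tab$model <- "univariate"
      tab$or_fmt <- sprintf("%.2f (%.2f-%.2f)", tab$or, tab$ci_low, tab$ci_high)
      tab[, c("model", "term", "unit", "or", "ci_low", "ci_high", "p", "or_fmt")]
    })
    wr(do.call(rbind, c(uni_rows, or_rows)), "table2_odds_ratios.csv")
  }
  wr(res$comparisons, "table3_discrimination.csv")
  if (!is.null(res$validation)) {
    vt <- do.call(rbind, lapply(names(res$validation), function(mid) {
      v <- res$validation[[mid]]
      data.frame(model = mid, apparent_c = v$apparent_c, optimism = v$optimism,
                 corrected_c = v$corrected_c,
                 calibration_slope = v$calibration_slope,
                 mae = v$mae, q90_ae = v$q90_ae, B = v$B,
                 n_skipped = v$n_skipped, stringsAsFactors = FALSE)
    }))
    wr(vt, "validation.csv")
  }
  if (!is.null(res$cutoff)) {
    wr(data.frame(cutoff = res$cutoff$cutoff,
                  sensitivity = res$cutoff$sensitivity,
                  specificity = res$cutoff$specificity,
                  youden = res$cutoff$youden), "cutoff_scan.csv")
  }
  writeLines(jsonlite::toJSON(res$manifest, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE),
             file.path(out_dir, "manifest.json"))
  writeLines(res$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
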