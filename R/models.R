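#' Predictor sets for the standard model specifications
#'
#' The suite of logistic specifications for in-hospital falls, all with age
#' and sex as covariates:
#' `m1` age + sex + STRATIFY; `m2` adds FI-lab to `m1`; `m3` replaces
#' STRATIFY by the six-item STRATIFY-including-FI-lab score; `m4` adds the
#' clinical frailty index to `m1`; `m5` age + sex + FI-lab + FI-clinical
#' (no STRATIFY); `m6` adds FI-clinical to `m2` (all three scores).
#'
#' @param model_id one of `"m1"` ... `"m6"`.
#' @param adjust optional extra covariates appended for sensitivity analyses,
#'   a subset of `c("polypharmacy", "cci")`.
#' @return character vector of predictor column names.
#' @export
model_terms <- function(model_id, adjust = NULL) {
  base <- switch(model_id,
    m1 = c("age", "sex", "stratify"),
    m2 = c("age", "sex", "stratify", "fi_lab"),
    m3 = c("age", "sex", "stratify_filab"),
    m4 = c("age", "sex", "stratify", "fi_clinical"),
    m5 = c("age", "sex", "fi_lab", "fi_clinical"),
    m6 = c("age", "sex", "stratify", "fi_lab", "fi_clinical"),
    stop("unknown model id: ", model_id))
  if (!is.null(adjust)) {
    bad <- setdiff(adjust, c("polypharmacy", "cci"))
    if (length(bad)) stop("unknown adjustment covariate(s): ",
                          paste(bad, collapse = ", "))
    base <- c(base, adjust)
  }
  base
}

# reporting unit for each term: FI indices per 0.1 unit, everything else per
# 1 unit (STRATIFY per point, age per year)
term_unit <- function(term) {
  ifelse(term %in% c("fi_lab", "fi_clinical"), 0.1, 1)
}

#' Fit a logistic fall-risk model
#'
#' Maximum-likelihood logistic regression of the fall outcome on a predictor
#' set, by iteratively reweighted least squares via [stats::glm()] with a
#' tight convergence tolerance. Sex is coded male = 1 (female reference).
#' Rows with a missing value in any required column are dropped
#' (complete-case; the count is recorded). Perfect or quasi-perfect
#' separation is detected from exploding coefficients or standard errors and
#' flagged rather than silently returned.
#'
#' @param data data.frame of per-admission scores (as from
#'   [compute_scores()] or [simulate_scores()]) containing `fell` and the
#'   predictor columns.
#' @param model a model id understood by [model_terms()], or `NULL` when
#'   `predictors` is given directly.
#' @param predictors explicit character vector of predictor columns
#'   (overrides `model`). May be `character(0)` for an intercept-only fit.
#' @param adjust optional sensitivity covariates, see [model_terms()].
#' @param outcome name of the binary outcome column, default `"fell"`.
#' @return an object of class `fall_fit`: the underlying `glm`, coefficient
#'   table, covariance matrix, `n`, `events`, `epv` (events per non-intercept
#'   predictor), `converged`, `separation`, and per-admission fitted
#'   probabilities.
#' @export
fit_fall_model <- function(data, model = "m2", predictors = NULL, adjust = NULL,
                           outcome = "fell") {
  if (is.null(predictors)) {
    predictors <- model_terms(model, adjust)
  } else {
    model <- model %||% "custom"
  }
  need <- c(outcome, predictors)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("data is missing column(s): ", paste(miss, collapse = ", "))
  df <- data[, need, drop = FALSE]
  complete <- stats::complete.cases(df)
  n_dropped <- sum(!complete)
  df <- df[complete, , drop = FALSE]
  y <- as.integer(as.logical(df[[outcome]]))
  if (all(y == 1) || all(y == 0)) {
    stop("outcome is constant: need at least one event and one non-event")
  }
  # sex enters as a male indicator (female reference); a plain numeric column
  # keeps single-sex subgroups estimable (the term is then aliased, not fatal)
  rhs_terms <- predictors
  if ("sex" %in% predictors) {
    df$sexmale <- as.integer(df$sex == "male")
    rhs_terms[rhs_terms == "sex"] <- "sexmale"
  }
  rhs <- if (length(rhs_terms)) paste(rhs_terms, collapse = " + ") else "1"
  form <- stats::as.formula(paste(outcome, "~", rhs))
  df[[outcome]] <- y
  # glm.fit's own separation/convergence chatter is superseded by the explicit
  # diagnostics below
  fit <- suppressWarnings(
    stats::glm(form, family = stats::binomial(), data = df,
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  beta <- stats::coef(fit)
  V <- stats::vcov(fit)   # aliased (rank-deficient) terms are absent here
  se <- stats::setNames(rep(NA_real_, length(beta)), names(beta))
  se[rownames(V)] <- sqrt(diag(V))
  separation <- any(abs(beta) > 15, na.rm = TRUE) || any(se > 50, na.rm = TRUE)
  converged <- isTRUE(fit$converged) && !separation
  if (separation) {
    warning("possible separation: coefficient or SE diverged; fit flagged unconverged")
  }
  n_pred <- length(predictors)
  structure(list(glm = fit, model_id = model, predictors = predictors,
                 outcome = outcome,
                 coefficients = beta, se = se, vcov = V,
                 n = nrow(df), events = sum(y),
                 epv = if (n_pred > 0) sum(y) / n_pred else NA_real_,
                 n_dropped = n_dropped,
                 converged = converged, separation = separation,
                 fitted = as.numeric(stats::fitted(fit)),
                 linear_predictor = as.numeric(fit$linear.predictors),
                 complete_rows = which(complete)),
            class = "fall_fit")
}

#' Odds ratio for one model term at a reporting unit
#'
#' `OR = exp(unit * beta)` with Wald 95% CI endpoints
#' `exp(unit * (beta +/- 1.959964 * SE))`. FI-lab and FI-clinical are
#' conventionally reported per 0.1 unit, STRATIFY per point.
#'
#' @param fit a [fit_fall_model()] result.
#' @param term coefficient name (e.g. `"fi_lab"`, `"stratify"`, `"sexmale"`).
#' @param unit reporting unit; default from [model_terms()] conventions.
#' @return named list `or`, `ci_low`, `ci_high`, `p`, `unit`.
#' @export
odds_ratio <- function(fit, term, unit = NULL) {
  stopifnot(inherits(fit, "fall_fit"))
  if (!term %in% names(fit$coefficients)) stop("unknown term: ", term)
  if (is.null(unit)) unit <- term_unit(term)
  b <- fit$coefficients[[term]]; s <- fit$se[[term]]
  qn <- stats::qnorm(0.975)
  list(or = exp(unit * b),
       ci_low = exp(unit * (b - qn * s)),
       ci_high = exp(unit * (b + qn * s)),
       p = 2 * stats::pnorm(-abs(b / s)),
       unit = unit)
}

#' Odds-ratio table for every non-intercept term
#'
#' @param fit a [fit_fall_model()] result.
#' @return data.frame with `term`, `unit`, `or`, `ci_low`, `ci_high`, `p`.
#' @export
odds_ratios <- function(fit) {
  stopifnot(inherits(fit, "fall_fit"))
  terms <- setdiff(names(fit$coefficients), "(Intercept)")
  rows <- lapply(terms, function(tm) {
    u <- if (tm == "sexmale") 1 else term_unit(tm)
    o <- odds_ratio(fit, tm, u)
    data.frame(term = tm, unit = u, or = o$or, ci_low = o$ci_low,
               ci_high = o$ci_high, p = o$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.fall_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Logistic fall-risk model '%s': %d admissions, %d falls (%.1f%%)\n",
              x$model_id, x$n, x$events, 100 * x$events / x$n))
  if (!x$converged) cat("  ** fit did not converge",
                        if (x$separation) "(possible separation)", "**\n")
  if (length(x$predictors)) {
    tab <- odds_ratios(x)
    tab$or <- round(tab$or, digits)
    tab$ci <- sprintf(paste0("(%.", digits, "f-%.", digits, "f)"),
                      tab$ci_low, tab$ci_high)
    tab$p <- signif(tab$p, 2)
    print(tab[, c("term", "unit", "or", "ci", "p")], row.names = FALSE)
  } else {
    cat("  (intercept only)\n")
  }
  invisible(x)
}

#' @export
summary.fall_fit <- function(object, ...) {
  x <- object
  cat(sprintf("Model '%s' | n = %d, events = %d (%.2f%%), EPV = %s\n",
              x$model_id, x$n, x$events, 100 * x$events / x$n,
              if (is.na(x$epv)) "n/a" else sprintf("%.1f", x$epv)))
  cat(sprintf("Deviance %.2f on %d df | AIC %.2f | converged: %s\n",
              x$glm$deviance, x$glm$df.residual, x$glm$aic, x$converged))
  if (x$n_dropped) cat("Dropped", x$n_dropped, "incomplete row(s)\n")
  print(x)
  r <- roc_auc(x$fitted, x$glm$y)
  cat(sprintf("Apparent AUROC %.3f (95%% CI %.3f-%.3f)\n", r$auc, r$ci[1], r$ci[2]))
  invisible(x)
}

#' @export
coef.fall_fit <- function(object, ...) object$coefficients

#' @export
vcov.fall_fit <- function(object, ...) object$vcov

#' @export
predict.fall_fit <- function(object, newdata = NULL,
                             type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    return(if (type == "response") object$fitted else object$linear_predictor)
  }
  if ("sex" %in% object$predictors && is.null(newdata$sexmale)) {
    newdata$sexmale <- as.integer(newdata$sex == "male")
  }
  as.numeric(stats::predict(object$glm, newdata = newdata, type = type))
}

#' @export
residuals.fall_fit <- function(object, ...) stats::residuals(object$glm, ...)

#' @export
simulate.fall_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$fitted
  out <- as.data.frame(replicate(nsim, stats::rbinom(length(p), 1L, p)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.fall_fit <- function(x, ...) {
  r <- roc_auc(x$fitted, x$glm$y)
  graphics::plot(r$curve$fpr, r$curve$tpr, type = "l",
                 xlab = "1 - specificity", ylab = "Sensitivity",
                 main = sprintf("Model '%s' ROC (AUROC %.3f)", x$model_id, r$auc),
                 ...)
  graphics::abline(0, 1, lty = 3)
  invisible(r)
}

#' Fit the univariate and multivariate model suite
#'
#' Fits `m1` ... `m6` (or a subset) plus, optionally, unadjusted univariate
#' fits for each risk score. Per-model failures are captured and reported
#' without aborting the suite. The events-per-variable guardrail is reported
#' for the primary model (`m2`: events / 4 predictors).
#'
#' @param data per-admission score data.frame (see [fit_fall_model()]).
#' @param models character vector of model ids, default all six.
#' @param univariate also fit single-predictor models for `stratify`,
#'   `fi_lab`, `fi_clinical` and `stratify_filab` (where present).
#' @param adjust sensitivity covariates appended to every multivariate model.
#' @return object of class `fall_model_suite`: named list `fits`, `uni`,
#'   `errors`, `epv` (for m2), `n`, `events`.
#' @export
run_model_suite <- function(data, models = paste0("m", 1:6),
                            univariate = TRUE, adjust = NULL) {
  fits <- list(); errors <- list()
  for (mid in models) {
    res <- tryCatch(fit_fall_model(data, model = mid, adjust = adjust),
                    error = function(e) e)
    if (inherits(res, "error")) errors[[mid]] <- conditionMessage(res)
    else fits[[mid]] <- res
  }
  uni <- list()
  if (univariate) {
    for (tm in intersect(c("stratify", "fi_lab", "fi_clinical", "stratify_filab"),
                         names(data))) {
      res <- tryCatch(fit_fall_model(data, model = paste0("uni_", tm),
                                     predictors = tm),
                      error = function(e) e)
      if (inherits(res, "error")) errors[[paste0("uni_", tm)]] <- conditionMessage(res)
      else uni[[tm]] <- res
    }
  }
  epv <- if (!is.null(fits$m2)) fits$m2$epv else NA_real_
  structure(list(fits = fits, uni = uni, errors = errors, epv = epv,
                 n = if (length(fits)) fits[[1]]$n else NA_integer_,
                 events = if (length(fits)) fits[[1]]$events else NA_integer_),
            class = "fall_model_suite")
}

#' @export
print.fall_model_suite <- function(x, ...) {
  cat(sprintf("Fall-risk model suite: %d models (n = %s, events = %s, EPV[m2] = %s)\n",
              length(x$fits), x$n, x$events,
              if (is.na(x$epv)) "n/a" else sprintf("%.1f", x$epv)))
  for (mid in names(x$fits)) {
    f <- x$fits[[mid]]
    tab <- odds_ratios(f)
    hl <- paste(sprintf("%s %.2f (%.2f-%.2f)", tab$term, tab$or,
                        tab$ci_low, tab$ci_high), collapse = ", ")
    cat(" ", mid, ":", hl, "\n")
  }
  for (mid in names(x$errors)) cat("  ", mid, ": ERROR ", x$errors[[mid]], "\n")
  invisible(x)
}

#' Refit the model suite within subgroups
#'
#' Partitions the cohort by age (below 75 versus 75 and older; 75 goes to
#' the older stratum) or by sex, and refits the requested models within each
#' stratum. A stratum with no events (or no non-events) is skipped with a
#' warning.
#'
#' @param data per-admission score data.frame.
#' @param by `"age"` or `"sex"`.
#' @param age_cut stratification age, default 75.
#' @param ... passed to [run_model_suite()].
#' @return named list of `fall_model_suite` objects, one per stratum, with a
#'   `sizes` attribute recording the stratum sizes.
#' @export
subgroup_suite <- function(data, by = c("age", "sex"), age_cut = 75, ...) {
  by <- match.arg(by)
  strata <- if (by == "age") {
    ifelse(data$age >= age_cut, paste0("age>=", age_cut), paste0("age<", age_cut))
  } else {
    as.character(data$sex)
  }
  out <- list()
  sizes <- table(strata)
  for (lv in sort(unique(strata))) {
    d <- data[strata == lv, , drop = FALSE]
    y <- as.logical(d$fell)
    if (!any(y) || all(y)) {
      warning("stratum '", lv, "' skipped: outcome has a single class")
      next
    }
    out[[lv]] <- run_model_suite(d, ...)
  }
  attr(out, "sizes") <- sizes
  out
}
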