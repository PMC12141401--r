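#' Bootstrap optimism-corrected internal validation
#'
#' Implements the enhanced (Efron/Harrell) bootstrap: for each of `B`
#' resamples drawn with replacement at the admission level, the model
#' specification is refit on the resample; the optimism of the c-statistic is
#' the mean of (c on the resample) minus (c of that refit evaluated on the
#' original data), and the corrected c-statistic is the apparent c minus this
#' optimism. The calibration slope is the mean, over resamples, of the
#' coefficient from regressing the original outcomes on the resample model's
#' linear predictor. Calibration error is summarized against the
#' optimism-corrected calibration curve: the apparent locally weighted
#' (lowess, span 2/3) curve of observed outcome versus predicted probability,
#' shifted by the mean bootstrap optimism of that curve, evaluated at each
#' admission's predicted probability; `mae` is the mean and `q90_ae` the 0.9
#' quantile of the absolute errors.
#'
#' Resamples on which the refit fails to converge (or separates) are skipped
#' and counted; a report with more than 5% skipped resamples is flagged
#' unstable.
#'
#' @param data per-admission score data.frame (see [fit_fall_model()]).
#' @param model model id passed to [fit_fall_model()].
#' @param predictors explicit predictor set (overrides `model`).
#' @param B number of bootstrap resamples (default 1000; below 50 a warning
#'   is issued).
#' @param seed integer RNG seed; mandatory for reproducibility.
#' @param adjust sensitivity covariates, see [model_terms()].
#' @param span lowess span for the calibration smoother.
#' @param indices optional list of `B` index vectors to use as the resamples
#'   (for reproduction or testing); when supplied, `B` is taken from its
#'   length.
#' @return object of class `validation_report`: `apparent_c`, `optimism`,
#'   `corrected_c` (= apparent - optimism), `calibration_slope`, `mae`,
#'   `q90_ae`, `median_ae`, `B`, `seed`, `n_skipped`, `unstable`, and the
#'   corrected calibration `curve`.
#' @export
validate_model <- function(data, model = "m2", predictors = NULL, B = 1000L,
                           seed, adjust = NULL, span = 2/3, indices = NULL) {
  if (missing(seed) || is.null(seed)) stop("validate_model requires an explicit seed")
  if (!is.null(indices)) B <- length(indices)
  B <- as.integer(B)
  if (B < 50L) warning("B below 50 gives an unreliable optimism estimate")

  full <- fit_fall_model(data, model = model, predictors = predictors,
                         adjust = adjust)
  if (!full$converged) stop("full-data model did not converge; nothing to validate")
  y <- full$glm$y
  n <- full$n
  p_hat <- full$fitted
  apparent_c <- auc_rank(p_hat, y)

  # design matrix reused across resamples (refits via glm.fit)
  X <- stats::model.matrix(full$glm)
  grid <- calibration_grid(p_hat)
  cal_app <- smooth_calibration(p_hat, y, grid, span)

  set.seed(as.integer(seed))
  if (is.null(indices)) {
    indices <- lapply(seq_len(B), function(b) sample.int(n, n, replace = TRUE))
  }
  opt_c <- rep(NA_real_, B)
  slopes <- rep(NA_real_, B)
  cal_opt <- matrix(NA_real_, length(grid), B)
  n_skipped <- 0L
  for (b in seq_len(B)) {
    idx <- indices[[b]]
    yb <- y[idx]
    if (all(yb == 1L) || all(yb == 0L)) { n_skipped <- n_skipped + 1L; next }
    fb <- tryCatch(
      suppressWarnings(stats::glm.fit(X[idx, , drop = FALSE], yb,
                                      family = stats::binomial(),
                                      control = list(epsilon = 1e-10, maxit = 100))),
      error = function(e) NULL)
    if (is.null(fb) || !fb$converged || any(abs(fb$coefficients) > 15)) {
      n_skipped <- n_skipped + 1L; next
    }
    p_bb <- fb$fitted.values
    lp_orig <- drop(X %*% fb$coefficients)
    p_ob <- stats::plogis(lp_orig)
    c_boot <- auc_rank(p_bb, yb)
    c_orig <- auc_rank(p_ob, y)
    opt_c[b] <- c_boot - c_orig
    sl <- tryCatch(
      suppressWarnings(stats::glm.fit(cbind(1, lp_orig), y,
                                      family = stats::binomial(),
                                      control = list(epsilon = 1e-10, maxit = 100))),
      error = function(e) NULL)
    slopes[b] <- if (is.null(sl)) NA_real_ else sl$coefficients[2]
    cal_opt[, b] <- smooth_calibration(p_bb, yb, grid, span) -
      smooth_calibration(p_ob, y, grid, span)
  }
  if (n_skipped > 0.05 * B) {
    warning(sprintf("%d of %d resamples skipped (>5%%); report flagged unstable",
                    n_skipped, B))
  }
  if (all(is.na(opt_c))) stop("no bootstrap resample converged")
  optimism <- mean(opt_c, na.rm = TRUE)
  corrected_curve <- cal_app - rowMeans(cal_opt, na.rm = TRUE)
  ae <- abs(eval_curve(grid, corrected_curve, p_hat) - p_hat)
  structure(list(model_id = full$model_id,
                 apparent_c = apparent_c, optimism = optimism,
                 corrected_c = apparent_c - optimism,
                 calibration_slope = mean(slopes, na.rm = TRUE),
                 mae = mean(ae),
                 q90_ae = unname(stats::quantile(ae, 0.9, type = 7)),
                 median_ae = unname(stats::median(ae)),
                 B = B, seed = as.integer(seed),
                 n_skipped = n_skipped, unstable = n_skipped > 0.05 * B,
                 curve = data.frame(predicted = grid,
                                    observed_corrected = corrected_curve),
                 n = n, events = full$events),
            class = "validation_report")
}

# evaluation grid for calibration curves: the observed predictions when few,
# otherwise an even sweep of their range
calibration_grid <- function(p_hat, max_points = 512L) {
  u <- sort(unique(p_hat))
  if (length(u) <= max_points) return(u)
  seq(min(u), max(u), length.out = max_points)
}

# interpolate a curve at xout; a single-point curve is a constant
eval_curve <- function(grid, vals, xout) {
  if (length(grid) < 2L) return(rep(vals[1], length(xout)))
  stats::approx(grid, vals, xout = xout, rule = 2, ties = mean)$y
}

# locally weighted calibration curve: lowess of outcome on predicted
# probability, evaluated at `grid` by interpolation; degenerate inputs
# (a single distinct prediction) fall back to the event rate
smooth_calibration <- function(predicted, observed, grid, span = 2/3) {
  if (length(unique(predicted)) < 2L) {
    return(rep(mean(observed), length(grid)))
  }
  sm <- stats::lowess(predicted, observed, f = span, iter = 0)
  stats::approx(sm$x, sm$y, xout = grid, rule = 2, ties = mean)$y
}

#' Calibration error against a smoothed observed-risk curve
#'
#' Estimates observed event probability by locally weighted regression
#' (lowess, fixed span, no robustness iterations) of the binary outcome on
#' the predicted probability, and summarizes the per-subject absolute
#' difference between the smoothed observed risk and the prediction. This is
#' the *apparent* calibration error; within [validate_model()] the same
#' summaries are computed against the optimism-corrected curve.
#'
#' @param predicted predicted probabilities in (0, 1); at least 50 subjects.
#' @param observed binary outcomes.
#' @param span lowess span, default 2/3.
#' @return list with `mae`, `q90_ae`, `median_ae`, and the smoothed `curve`.
#' @export
calibration_error <- function(predicted, observed, span = 2/3) {
  if (length(predicted) != length(observed)) {
    stop("predicted and observed differ in length")
  }
  if (length(predicted) < 50L) {
    stop("fewer than 50 subjects: calibration smoother unreliable")
  }
  check_probs(predicted)
  y <- as.integer(as.logical(observed))
  grid <- calibration_grid(predicted)
  sm <- smooth_calibration(predicted, y, grid, span)
  ae <- abs(eval_curve(grid, sm, predicted) - predicted)
  list(mae = mean(ae),
       q90_ae = unname(stats::quantile(ae, 0.9, type = 7)),
       median_ae = unname(stats::median(ae)),
       curve = data.frame(predicted = grid, observed_smoothed = sm))
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Internal validation of model '%s' (B = %d, seed = %d)\n",
              x$model_id, x$B, x$seed))
  cat(sprintf("  apparent c %.4f | optimism %.4f | corrected c %.4f\n",
              x$apparent_c, x$optimism, x$corrected_c))
  cat(sprintf("  calibration slope %.3f | MAE %.4f | 0.9 quantile AE %.4f\n",
              x$calibration_slope, x$mae, x$q90_ae))
  if (x$n_skipped) cat(sprintf("  %d resample(s) skipped%s\n", x$n_skipped,
                               if (x$unstable) " — UNSTABLE" else ""))
  invisible(x)
}
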