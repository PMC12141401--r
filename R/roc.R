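#' ROC curve and AUROC by pair counting
#'
#' The AUROC is computed as the Mann-Whitney pair statistic — the fraction of
#' (event, non-event) pairs in which the event subject scores higher, with
#' half credit for ties — via midranks. The full ROC curve (one point per
#' distinct score value) is also returned; its trapezoidal integral equals
#' the pair statistic to machine precision, which the object records for
#' verification. The standard error is the DeLong structural-components
#' estimate and the 95% CI is normal-approximation, clipped to \[0, 1\].
#'
#' @param scores numeric risk scores, higher = riskier.
#' @param labels binary outcomes (logical or 0/1); both classes must be
#'   present.
#' @return an object of class `roc_result` with `auc`, `auc_trapezoid`, `se`,
#'   `ci`, `curve` (data.frame `threshold`, `fpr`, `tpr`), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  d <- check_scores_labels(scores, labels)
  comp <- delong_components(d$scores, d$labels)
  n1 <- comp$m; n0 <- comp$n
  # curve: sweep thresholds from high to low, one point per distinct value
  ord <- order(d$scores, decreasing = TRUE)
  s <- d$scores[ord]; y <- d$labels[ord]
  cum_tp <- cumsum(y); cum_fp <- cumsum(1 - y)
  keep <- which(c(s[-1] != s[-length(s)], TRUE))
  curve <- data.frame(threshold = c(Inf, s[keep]),
                      fpr = c(0, cum_fp[keep] / n0),
                      tpr = c(0, cum_tp[keep] / n1))
  auc_trap <- sum(diff(curve$fpr) *
                    (curve$tpr[-1] + curve$tpr[-nrow(curve)]) / 2)
  se <- sqrt(stats::var(comp$v10) / n1 + stats::var(comp$v01) / n0)
  ci <- pmin(pmax(comp$auc + c(-1, 1) * stats::qnorm(0.975) * se, 0), 1)
  structure(list(auc = comp$auc, auc_trapezoid = auc_trap, se = se, ci = ci,
                 curve = curve, n_pos = n1, n_neg = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUROC %.4f (95%% CI %.4f-%.4f), %d events / %d non-events\n",
              x$auc, x$ci[1], x$ci[2], x$n_pos, x$n_neg))
  invisible(x)
}

check_scores_labels <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  labels <- as.integer(as.logical(labels))
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (!any(labels == 1) || !any(labels == 0)) {
    stop("both outcome classes must be present")
  }
  list(scores = scores, labels = labels)
}

# DeLong structural components (placement values) via midranks, O(n log n):
# v10[i] = mean over non-events of [score_i > score_j] + 0.5 [tie],
# v01[j] = analogous over events; auc = mean(v10) = mean(v01).
delong_components <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  auc <- (sum(r_all[seq_len(m)]) - m * (m + 1) / 2) / (as.numeric(m) * n)
  list(auc = auc, v10 = v10, v01 = v01, m = m, n = n)
}

# rank-only AUC (no curve, no components) for hot loops
auc_rank <- function(scores, labels) {
  n1 <- sum(labels); n0 <- length(labels) - n1
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (as.numeric(n1) * n0)
}

#' Compare two paired AUROCs by the DeLong method
#'
#' Both scores must be measured on the same subjects. The covariance of the
#' two AUROC estimates is built from the DeLong structural components, the
#' difference is tested against a standard normal, and per-AUC 95% CIs come
#' from the same covariance matrix. When the variance of the difference is
#' numerically zero (for example identical score vectors) the comparison is
#' flagged degenerate and reported with `delta = 0`, `p = 1`.
#'
#' @param scores_a,scores_b paired numeric scores.
#' @param labels binary outcomes.
#' @return an object of class `delong_comparison`: `auc_a`, `auc_b`, `ci_a`,
#'   `ci_b`, `delta`, `se_delta`, `z`, `p`, `cov` (2x2), `degenerate`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b)) {
    stop("scores must be paired on the same subjects")
  }
  d <- check_scores_labels(scores_a, labels)
  db <- check_scores_labels(scores_b, labels)
  ca <- delong_components(d$scores, d$labels)
  cb <- delong_components(db$scores, db$labels)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  S <- s10 / ca$m + s01 / ca$n
  var_delta <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  delta <- ca$auc - cb$auc
  degenerate <- var_delta < 1e-15
  if (degenerate) {
    z <- 0; p <- 1; delta <- 0; se_delta <- 0
  } else {
    se_delta <- sqrt(var_delta)
    z <- delta / se_delta
    p <- 2 * stats::pnorm(-abs(z))
  }
  qn <- stats::qnorm(0.975)
  structure(list(auc_a = ca$auc, auc_b = cb$auc,
                 ci_a = pmin(pmax(ca$auc + c(-1, 1) * qn * sqrt(S[1, 1]), 0), 1),
                 ci_b = pmin(pmax(cb$auc + c(-1, 1) * qn * sqrt(S[2, 2]), 0), 1),
                 delta = delta, se_delta = se_delta, z = z, p = p, cov = S,
                 degenerate = degenerate),
            class = "delong_comparison")
}

#' @export
print.delong_comparison <- function(x, ...) {
  cat(sprintf("DeLong paired AUROC comparison\n  AUC A %.4f vs AUC B %.4f, delta %+.4f, z = %.3f, p = %.4g%s\n",
              x$auc_a, x$auc_b, x$delta, x$z, x$p,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Category-free (continuous) net reclassification improvement
#'
#' For events, the net proportion whose predicted risk rises under the new
#' model; for non-events, the net proportion whose predicted risk falls; the
#' NRI is their sum (range -2 to 2). Exact ties (`p_new == p_old`) count for
#' neither direction. The default CI and p-value use the asymptotic variance
#' of the two net proportions; a subject-resampling bootstrap CI is available
#' as an option.
#'
#' @param p_old,p_new paired predicted probabilities in \[0, 1\].
#' @param labels binary outcomes.
#' @param ci `"asymptotic"` (default) or `"bootstrap"`.
#' @param B bootstrap resamples when `ci = "bootstrap"`.
#' @param seed RNG seed for the bootstrap.
#' @return object of class `reclass_result`: `statistic = "nri"`, `estimate`,
#'   `events`, `nonevents`, `se`, `ci`, `p`, `method`.
#' @export
continuous_nri <- function(p_old, p_new, labels, ci = c("asymptotic", "bootstrap"),
                           B = 1000, seed = 1L) {
  ci <- match.arg(ci)
  if (length(p_old) != length(p_new)) stop("p_old and p_new differ in length")
  if (length(p_old) != length(labels)) stop("probabilities and labels differ in length")
  check_probs(p_old); check_probs(p_new)
  y <- as.integer(as.logical(labels))
  if (!any(y == 1) || !any(y == 0)) stop("both outcome classes must be present")
  est <- nri_estimate(p_old, p_new, y)
  se <- sqrt(est$var_events + est$var_nonevents)
  z <- if (se > 0) est$nri / se else 0
  p <- if (se > 0) 2 * stats::pnorm(-abs(z)) else 1
  interval <- if (ci == "asymptotic") {
    est$nri + c(-1, 1) * stats::qnorm(0.975) * se
  } else {
    set.seed(seed)
    boots <- replicate(B, {
      i <- sample.int(length(y), replace = TRUE)
      nri_estimate(p_old[i], p_new[i], y[i])$nri
    })
    unname(stats::quantile(boots, c(0.025, 0.975), type = 7))
  }
  structure(list(statistic = "nri", estimate = est$nri,
                 events = est$events, nonevents = est$nonevents,
                 se = se, ci = interval, p = p, method = ci),
            class = "reclass_result")
}

nri_estimate <- function(p_old, p_new, y) {
  e <- y == 1
  n_e <- sum(e); n_ne <- sum(!e)
  up_e <- mean(p_new[e] > p_old[e]); down_e <- mean(p_new[e] < p_old[e])
  up_ne <- mean(p_new[!e] > p_old[!e]); down_ne <- mean(p_new[!e] < p_old[!e])
  ev <- up_e - down_e
  ne <- down_ne - up_ne
  list(nri = ev + ne, events = ev, nonevents = ne,
       var_events = (up_e + down_e - ev^2) / n_e,
       var_nonevents = (up_ne + down_ne - ne^2) / n_ne)
}

check_probs <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("probabilities must lie in [0, 1]")
}

#' Integrated discrimination improvement
#'
#' The IDI is the change, from old to new model, in the gap between the mean
#' predicted risk of events and of non-events (range -1 to 1). The standard
#' error comes from the paired differences `p_new - p_old` within each class.
#'
#' @inheritParams continuous_nri
#' @return object of class `reclass_result` with `statistic = "idi"`.
#' @export
idi <- function(p_old, p_new, labels) {
  if (length(p_old) != length(p_new)) stop("p_old and p_new differ in length")
  if (length(p_old) != length(labels)) stop("probabilities and labels differ in length")
  check_probs(p_old); check_probs(p_new)
  y <- as.integer(as.logical(labels))
  if (!any(y == 1) || !any(y == 0)) stop("both outcome classes must be present")
  delta <- p_new - p_old
  e <- y == 1
  est <- mean(delta[e]) - mean(delta[!e])
  se <- sqrt(stats::var(delta[e]) / sum(e) + stats::var(delta[!e]) / sum(!e))
  z <- if (se > 0) est / se else 0
  p <- if (se > 0) 2 * stats::pnorm(-abs(z)) else 1
  structure(list(statistic = "idi", estimate = est,
                 events = mean(delta[e]), nonevents = mean(delta[!e]),
                 se = se, ci = est + c(-1, 1) * stats::qnorm(0.975) * se,
                 p = p, method = "asymptotic"),
            class = "reclass_result")
}

#' @export
print.reclass_result <- function(x, ...) {
  cat(sprintf("%s %.4f (95%% CI %.4f to %.4f), p = %.4g [%s]\n",
              toupper(x$statistic), x$estimate, x$ci[1], x$ci[2], x$p, x$method))
  invisible(x)
}

#' Optimal binary cutpoint by the Youden index
#'
#' Scans the midpoints between consecutive distinct observed score values and
#' returns the cutpoint maximizing J = sensitivity + specificity - 1, where a
#' subject is called positive when its score exceeds the cutpoint. Ties on J
#' are broken toward the lower cutpoint. With a single distinct score value
#' there is no informative threshold and J = 0 is reported at that value.
#'
#' @param scores numeric risk scores.
#' @param labels binary outcomes.
#' @return list with `cutoff`, `sensitivity`, `specificity`, `youden`.
#' @export
optimal_cutoff <- function(scores, labels) {
  d <- check_scores_labels(scores, labels)
  s <- sort(unique(d$scores))
  if (length(s) == 1L) {
    return(list(cutoff = s, sensitivity = 0, specificity = 1, youden = 0))
  }
  # midpoints between consecutive distinct values, plus the two degenerate
  # boundary thresholds (call everyone / no one positive, J = 0) so an
  # uninformative score never yields a negative "optimum"
  cand <- c(s[1] - 1, (s[-1] + s[-length(s)]) / 2, s[length(s)] + 1)
  pos <- sort(d$scores[d$labels == 1]); neg <- sort(d$scores[d$labels == 0])
  sens <- 1 - findInterval(cand, pos) / length(pos)
  spec <- findInterval(cand, neg) / length(neg)
  J <- sens + spec - 1
  best <- which.max(J)   # first maximum = lowest cutpoint
  list(cutoff = cand[best], sensitivity = sens[best],
       specificity = spec[best], youden = J[best])
}
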