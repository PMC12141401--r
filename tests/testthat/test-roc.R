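test_that("AUROC matches hand-enumerable cases", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1.0)
  expect_equal(roc_auc(c(1, 3, 2, 4), c(0, 0, 1, 1))$auc, 0.75)
  expect_equal(roc_auc(rep(2, 10), rep(c(0, 1), 5))$auc, 0.5)  # all ties
  expect_equal(roc_auc(c(4, 3, 2, 1), c(1, 1, 0, 0))$auc, 1.0)
  expect_error(roc_auc(1:4, rep(1, 4)), "both outcome classes")
})

test_that("pair-count AUC equals the trapezoid integral and brute force", {
  set.seed(5)
  for (i in 1:300) {
    n <- sample(4:12, 1)
    y <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- sample(1:5, n, replace = TRUE)  # heavy ties on purpose
    r <- roc_auc(s, y)
    expect_lt(abs(r$auc - r$auc_trapezoid), 1e-12)
    expect_lt(abs(r$auc - auc_brute(s, y)), 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(6)
  s <- rnorm(200); y <- rbinom(200, 1, plogis(s))
  base <- roc_auc(s, y)$auc
  for (f in list(function(x) 3 * x - 7, exp, function(x) x^3,
                 function(x) rank(x, ties.method = "average"))) {
    expect_equal(roc_auc(f(s), y)$auc, base)
  }
})

test_that("AUC and DeLong agree with the independent pROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  n <- 400
  y <- rbinom(n, 1, 0.3)
  s1 <- y + rnorm(n); s2 <- 0.5 * y + rnorm(n)
  r <- roc_auc(s1, y)
  pr <- pROC::roc(y, s1, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  ci <- pROC::ci.auc(pr, method = "delong")
  expect_equal(r$ci, as.numeric(ci[c(1, 3)]), tolerance = 1e-9)

  dt <- delong_test(s1, s2, y)
  pt <- pROC::roc.test(pROC::roc(y, s1, quiet = TRUE, direction = "<"),
                       pROC::roc(y, s2, quiet = TRUE, direction = "<"),
                       method = "delong", paired = TRUE)
  expect_equal(dt$p, as.numeric(pt$p.value), tolerance = 1e-9)
})

test_that("DeLong comparison degenerates gracefully and respects rank invariance", {
  set.seed(7)
  s <- rnorm(100); y <- rbinom(100, 1, plogis(s))
  same <- delong_test(s, s, y)
  expect_equal(same$delta, 0)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)

  mono <- delong_test(s, exp(s), y)  # identical rankings
  expect_equal(mono$auc_a, mono$auc_b)
  expect_equal(mono$delta, 0)
})

test_that("DeLong single-AUC variance agrees with a bootstrap oracle", {
  set.seed(9)
  n <- 30
  y <- rep(c(0, 1), times = c(18, 12))
  s <- y * 0.8 + rnorm(n)
  r <- roc_auc(s, y)
  boots <- replicate(20000, {
    i <- sample.int(n, replace = TRUE)
    if (length(unique(y[i])) < 2) NA_real_
    else frailtyfalls:::auc_rank(s[i], y[i])
  })
  se_boot <- sd(boots, na.rm = TRUE)
  expect_lt(abs(r$se - se_boot) / se_boot, 0.15)
})

test_that("continuous NRI matches direct enumeration", {
  # 4 events (3 up, 1 down), 6 non-events (4 down, 2 up)
  y <- c(rep(1, 4), rep(0, 6))
  p_old <- rep(0.5, 10)
  p_new <- c(0.6, 0.7, 0.8, 0.4,   # events: 3 up, 1 down
             0.4, 0.3, 0.2, 0.1, 0.6, 0.7)  # non-events: 4 down, 2 up
  r <- continuous_nri(p_old, p_new, y)
  expect_lt(abs(r$estimate - ((3 - 1) / 4 + (4 - 2) / 6)), 1e-12)
  expect_lt(abs(r$events - 0.5), 1e-12)
  expect_lt(abs(r$nonevents - 1 / 3), 1e-12)
  expect_equal(r$estimate, r$events + r$nonevents)

  # ties count for neither direction
  p_tied <- p_new; p_tied[1] <- 0.5
  r2 <- continuous_nri(p_old, p_tied, y)
  expect_lt(abs(r2$events - ((2 - 1) / 4)), 1e-12)
})

test_that("NRI bounds and self-comparison", {
  set.seed(14)
  y <- c(rep(1, 5), rep(0, 5))
  p <- runif(10, 0.15, 0.85)
  self <- continuous_nri(p, p, y)
  expect_equal(self$estimate, 0)
  # all events up, all non-events down -> exactly 2
  up <- p + 0.1; dn <- p - 0.1
  best <- continuous_nri(p, ifelse(y == 1, up, dn), y)
  expect_equal(best$estimate, 2)
  worst <- continuous_nri(p, ifelse(y == 1, dn, up), y)
  expect_equal(worst$estimate, -2)
})

test_that("IDI matches hand arithmetic and self-comparison is zero", {
  y <- c(1, 1, 0, 0)
  p_old <- c(0.2, 0.4, 0.3, 0.1)
  p_new <- c(0.3, 0.5, 0.2, 0.1)
  r <- idi(p_old, p_new, y)
  expect_lt(abs(r$estimate - 0.15), 1e-12)
  self <- idi(p_old, p_old, y)
  expect_equal(self$estimate, 0)
  expect_equal(self$p, 1)
  expect_error(idi(p_old[-1], p_new, y), "length")
  expect_error(idi(p_old + 1, p_new, y), "\\[0, 1\\]")
})

test_that("apparent IDI of an added noise predictor shows a small positive bias", {
  set.seed(15)
  vals <- replicate(60, {
    d <- logistic_testdata(400, -2, c(1), seed = sample.int(1e6, 1))
    d$z <- rnorm(400)
    f0 <- fit_fall_model(d, predictors = "x1")
    f1 <- fit_fall_model(d, predictors = c("x1", "z"))
    idi(f0$fitted, f1$fitted, d$fell)$estimate
  })
  # likelihood maximization raises the in-sample IDI up to solver noise, and
  # the mean is a small positive overfitting bias
  expect_true(all(vals > -1e-3))
  expect_gt(mean(vals), 0)
  expect_lt(mean(vals), 0.02)
})

test_that("Youden cutpoint equals exhaustive threshold search", {
  set.seed(18)
  for (i in 1:50) {
    y <- sample(c(0, 1), 10, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- round(runif(10), 2)
    res <- optimal_cutoff(s, y)
    # brute force over a dense threshold sweep
    grid <- seq(min(s) - 0.1, max(s) + 0.1, by = 0.001)
    J <- sapply(grid, function(c0) {
      mean(s[y == 1] > c0) + mean(s[y == 0] <= c0) - 1
    })
    expect_equal(res$youden, max(J), tolerance = 1e-12)
    expect_equal(res$sensitivity + res$specificity - 1, res$youden)
  }
})

test_that("Youden edge cases: perfect separation and all-tied scores", {
  sep <- optimal_cutoff(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(sep$youden, 1)
  expect_equal(sep$cutoff, 6.5)  # midpoint between the classes
  tied <- optimal_cutoff(rep(3, 8), rep(c(0, 1), 4))
  expect_equal(tied$youden, 0)
})

test_that("ties on the Youden index break toward the lower cutpoint", {
  # two thresholds reach J = 0.5; the lower one must be returned
  s <- c(1, 2, 3, 4)
  y <- c(0, 1, 0, 1)
  res <- optimal_cutoff(s, y)
  expect_equal(res$cutoff, 1.5)
})
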