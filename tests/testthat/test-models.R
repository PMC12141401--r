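test_that("intercept-only fit on a balanced outcome recovers logit(0.5) = 0", {
  d <- data.frame(fell = rep(c(TRUE, FALSE), 25))
  f <- fit_fall_model(d, predictors = character(0))
  expect_equal(unname(coef(f)[1]), 0, tolerance = 1e-8)
  expect_equal(unique(round(f$fitted, 10)), 0.5)
  expect_true(is.na(f$epv))
})

test_that("single binary predictor matches the closed-form 2x2 oracle", {
  # 2x2 cell counts (exposed/unexposed x event/non-event)
  cells <- list(c(a = 12, b = 30, c = 7, d = 51),
                c(a = 5, b = 9, c = 13, d = 41))
  for (cc in cells) {
    d <- data.frame(
      x = rep(c(1, 1, 0, 0), times = cc),
      fell = rep(c(1, 0, 1, 0), times = cc))
    f <- fit_fall_model(d, predictors = "x")
    log_or <- log(cc["a"] * cc["d"] / (cc["b"] * cc["c"]))
    se <- sqrt(sum(1 / cc))
    expect_lt(abs(coef(f)[["x"]] - log_or), 1e-6)
    expect_lt(abs(f$se[["x"]] - se), 1e-5)
    o <- odds_ratio(f, "x", unit = 1)
    expect_equal(o$or, exp(coef(f)[["x"]]))
    expect_equal(o$ci_low, exp(coef(f)[["x"]] - qnorm(0.975) * f$se[["x"]]))
  }
})

test_that("odds-ratio rescaling: beta = ln 2 per unit gives 2^0.1 per 0.1 unit", {
  d <- logistic_testdata(5000, -2, log(2), seed = 2)
  f <- fit_fall_model(d, predictors = "x1")
  b <- coef(f)[["x1"]]
  o <- odds_ratio(f, "x1", unit = 0.1)
  expect_equal(o$or, exp(b)^0.1)
  # exact algebra check at beta = ln 2
  expect_equal(exp(0.1 * log(2)), 2^0.1)
})

test_that("fitted-probability mean equals the event rate (score equation)", {
  d <- simulate_scores(sim_config(n = 3000, seed = 17))
  for (mid in c("m1", "m2", "m5", "m6")) {
    f <- fit_fall_model(d, mid)
    expect_true(f$converged)
    expect_lt(abs(mean(f$fitted) - mean(f$glm$y)), 1e-8)
    expect_true(all(f$fitted > 0 & f$fitted < 1))
  }
})

test_that("nested models never increase deviance: m1 in m2 in m6, m1 in m4 in m6", {
  d <- simulate_scores(sim_config(n = 4000, seed = 23))
  dev <- sapply(paste0("m", c(1, 2, 4, 6)), function(m)
    fit_fall_model(d, m)$glm$deviance)
  expect_lte(dev[["m2"]], dev[["m1"]])
  expect_lte(dev[["m6"]], dev[["m2"]])
  expect_lte(dev[["m4"]], dev[["m1"]])
  expect_lte(dev[["m6"]], dev[["m4"]])
})

test_that("constant outcome errors; separation is flagged, not returned silently", {
  d <- data.frame(fell = rep(TRUE, 20), x = rnorm(20))
  expect_error(fit_fall_model(d, predictors = "x"), "constant")
  sep <- data.frame(x = c(rep(0, 20), rep(1, 20)),
                    fell = c(rep(FALSE, 20), rep(TRUE, 20)))
  expect_warning(f <- fit_fall_model(sep, predictors = "x"), "separation")
  expect_false(f$converged)
  expect_true(f$separation)
})

test_that("parameter recovery on simulated cohorts stays within 3 SEs", {
  cfg <- sim_config(n = 20000, seed = 41)
  d <- simulate_scores(cfg)
  f <- fit_fall_model(d, "m2")
  truth <- c(age = cfg$outcome$age, sexmale = cfg$outcome$male,
             stratify = cfg$outcome$stratify,
             fi_lab = cfg$outcome$fi_lab / 0.1)  # per-0.1 coef on unit scale
  for (tm in names(truth)) {
    expect_lt(abs(coef(f)[[tm]] - truth[[tm]]), 3 * f$se[[tm]])
  }
})

test_that("model term sets follow the specification lattice", {
  expect_equal(model_terms("m1"), c("age", "sex", "stratify"))
  expect_equal(model_terms("m2"), c("age", "sex", "stratify", "fi_lab"))
  expect_equal(model_terms("m3"), c("age", "sex", "stratify_filab"))
  expect_equal(model_terms("m5"), c("age", "sex", "fi_lab", "fi_clinical"))
  expect_equal(model_terms("m6"),
               c("age", "sex", "stratify", "fi_lab", "fi_clinical"))
  expect_equal(model_terms("m2", adjust = "cci"),
               c("age", "sex", "stratify", "fi_lab", "cci"))
  expect_error(model_terms("m7"), "unknown model")
  expect_error(model_terms("m2", adjust = "statins"), "unknown adjustment")
})

test_that("suite reports EPV for the primary model and survives per-model failure", {
  d <- simulate_scores(sim_config(n = 3000, seed = 29))
  d$stratify_filab <- NULL   # m3 cannot be fitted
  suite <- run_model_suite(d, models = c("m1", "m2", "m3"))
  expect_named(suite$fits, c("m1", "m2"))
  expect_match(suite$errors$m3, "stratify_filab")
  expect_equal(suite$epv, suite$events / 4)
})

test_that("subgroup strata partition the cohort; age 75 joins the older stratum", {
  d <- simulate_scores(sim_config(n = 5000, seed = 59))
  sub <- subgroup_suite(d, by = "age", models = "m2", univariate = FALSE)
  sizes <- attr(sub, "sizes")
  expect_equal(sum(sizes), nrow(d))
  expect_equal(unname(sizes[["age>=75"]]), sum(d$age >= 75))
  # every 75-year-old is in the older stratum
  expect_equal(sub[["age>=75"]]$fits$m2$n, sum(d$age >= 75))

  # degenerate partition: a single all-inclusive stratum reproduces the pooled fit
  d$sex <- "male"
  pooled <- fit_fall_model(d, "m2")
  one <- subgroup_suite(d, by = "sex", models = "m2", univariate = FALSE)
  expect_length(one, 1L)
  cs <- coef(one$male$fits$m2); cp <- coef(pooled)
  expect_equal(cs[!is.na(cs)], cp[!is.na(cp)])
})

test_that("eventless strata are skipped with a warning", {
  d <- simulate_scores(sim_config(n = 400, seed = 61))
  d$fell[d$sex == "female"] <- FALSE
  expect_warning(sub <- subgroup_suite(d, by = "sex", models = "m1",
                                       univariate = FALSE),
                 "skipped")
  expect_false("female" %in% names(sub))
})

test_that("fall_fit methods: predict, residuals, simulate, plot", {
  d <- simulate_scores(sim_config(n = 2000, seed = 67))
  f <- fit_fall_model(d, "m2")
  expect_equal(predict(f), f$fitted)
  expect_equal(predict(f, newdata = d[1:5, ]), f$fitted[1:5])
  expect_length(residuals(f), f$n)
  sims <- simulate(f, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(f$n, 2L))
  expect_true(all(unlist(sims) %in% 0:1))
  pdf(NULL); on.exit(dev.off())
  r <- plot(f)
  expect_s3_class(r, "roc_result")
})
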