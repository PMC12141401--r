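test_that("reference-interval flags treat limits as inclusive", {
  p <- mini_panel()
  expect_equal(flag_abnormal(140, "sodium", "male", p), 0L)
  expect_equal(flag_abnormal(130, "sodium", "male", p), 1L)
  expect_equal(flag_abnormal(135, "sodium", "female", p), 0L)  # boundary normal
  expect_equal(flag_abnormal(145, "sodium", "male", p), 0L)
  expect_equal(flag_abnormal(145.0001, "sodium", "male", p), 1L)
  # sex-specific limits: 12.5 g/dL is low for a man, normal for a woman
  expect_equal(flag_abnormal(12.5, "hemoglobin", "male", p), 1L)
  expect_equal(flag_abnormal(12.5, "hemoglobin", "female", p), 0L)
  expect_error(flag_abnormal(NaN, "sodium", "male", p), "non-finite")
  expect_error(flag_abnormal(140, "troponin", "male", p), "not in panel")
})

test_that("FI-lab is abnormal/measured with a 70% eligibility floor", {
  panel <- default_panel()
  a <- panel$analytes
  # female-resolved limits (some analytes declare only sex-specific intervals)
  lo <- ifelse(is.na(a$lower), a$lower_female, a$lower)
  hi <- ifelse(is.na(a$upper), a$upper_female, a$upper)
  mid <- (lo + hi) / 2
  low <- lo - abs(lo) * 0.5 - 1

  # 35 measured, 7 abnormal -> 0.2 at full measured ratio
  vals <- mid; vals[1:7] <- low[1:7]
  r <- fi_lab_score(vals, a$analyte_id, "female", panel)
  expect_equal(r$fi_lab, 0.2)
  expect_equal(r$measured_ratio, 1.0)

  # 24 measured: 24/35 < 0.7 -> ineligible
  r24 <- fi_lab_score(vals[1:24], a$analyte_id[1:24], "female", panel)
  expect_true(is.na(r24$fi_lab))
  expect_equal(r24$measured_ratio, 24 / 35)

  # 25 measured, 10 abnormal -> eligible at exactly 25/35
  vals25 <- mid[1:25]; vals25[1:10] <- low[1:10]
  r25 <- fi_lab_score(vals25, a$analyte_id[1:25], "female", panel)
  expect_equal(r25$fi_lab, 0.4)
  expect_equal(r25$measured_ratio, 25 / 35)

  expect_error(fi_lab_score(c(140, 141), c("sodium", "sodium"), "male",
                            default_panel()),
               "first-result")
})

test_that("FI-lab banding and binarization agree at the stated boundaries", {
  expect_equal(as.character(band_fi_lab(c(0.24, 0.25, 0.31, 0.40, 0.401))),
               c("low", "mid", "mid", "mid", "high"))
  expect_error(band_fi_lab(1.2), "outside")

  expect_equal(binarize_fi_lab(c(0.4, 0.41)), c(0L, 1L))
  expect_equal(binarize_fi_lab(0.35, cutoff = 0.345), 1L)
  expect_equal(binarize_fi_lab(0.345, cutoff = 0.345), 0L)

  # band 'high' iff binary = 1 at the 0.4 cutoff, over a dense sweep
  s <- seq(0, 1, by = 0.001)
  expect_equal(band_fi_lab(s) == "high", binarize_fi_lab(s) == 1L)
})

test_that("clinical frailty index divides deficit sum by items assessed", {
  expect_equal(fi_clinical_score(rep(0, 40)), 0)
  v <- c(rep(1, 4), rep(0.5, 4), rep(0, 32))
  expect_equal(fi_clinical_score(v), 6 / 40)
  # 31 of 40 non-missing: 77.5% < 80% -> ineligible
  v31 <- c(rep(0.5, 31), rep(NA, 9))
  expect_true(is.na(fi_clinical_score(v31)))
  # 32 of 40: exactly 80% -> eligible, denominator is items assessed
  v32 <- c(rep(0.5, 32), rep(NA, 8))
  expect_equal(fi_clinical_score(v32), 0.5)
  expect_error(fi_clinical_score(c(0.3, rep(0, 39))), "\\{0, 0.5, 1\\}")
})

test_that("STRATIFY, STRATIFY+FI-lab and polypharmacy counts behave", {
  items <- c(history_of_falls = FALSE, mental_status = FALSE, vision = FALSE,
             toileting = FALSE, mobility = FALSE)
  expect_equal(stratify_score(items), 0L)
  expect_equal(stratify_score(!items), 5L)
  items["history_of_falls"] <- TRUE
  expect_equal(stratify_score(items), 1L)
  expect_error(stratify_score(items[-2]), "missing STRATIFY")

  expect_equal(stratify_plus_filab(5L, 0.5), 6L)
  expect_equal(stratify_plus_filab(0L, 0.4), 0L)   # 0.4 itself scores no point
  expect_equal(stratify_plus_filab(2L, 0.45), 3L)
  expect_true(is.na(stratify_plus_filab(2L, NA_real_)))  # ineligible propagates

  meds <- c(antihypertensive = FALSE, antidiabetic = FALSE,
            antithrombotic = FALSE, sleep = FALSE, antipsychotic = FALSE,
            nsaid = FALSE)
  expect_equal(polypharmacy_score(meds), 0L)
  expect_equal(polypharmacy_score(!meds), 6L)
  meds[c("antihypertensive", "nsaid")] <- TRUE
  expect_equal(polypharmacy_score(meds), 2L)
})

test_that("compute_scores matches per-admission hand computation on the fixture", {
  sc <- compute_scores(mini_cohort(), n_fic_items = 5L)
  # A1 (male): sodium 130 abnormal; K 4.1, Hb 14.2, Alb 3.9 normal -> 1/4
  expect_equal(sc$fi_lab[1], 1 / 4)
  expect_equal(sc$measured_ratio[1], 4 / 5)
  # A2 (female): K 5.5 high, Hb 11.0 low (female limit 12) -> 2/4
  expect_equal(sc$fi_lab[2], 2 / 4)
  # A3 (male): Alb 2.9 low, CRP 1.8 high -> 2/4
  expect_equal(sc$fi_lab[3], 2 / 4)
  # deficits: 4 of 5 items assessed = 80% eligible
  expect_equal(sc$fi_clinical, c(0.5 / 4, 0, 2.5 / 4))
  expect_equal(sc$stratify, c(1L, 1L, 2L))
  expect_equal(sc$polypharmacy, c(2L, 2L, 1L))
  expect_equal(sc$stratify_filab, c(1L, 2L, 3L))
  # A3 carries metastatic (C78) + primary (C18) cancer codes -> weight 6 only
  expect_equal(sc$cci, c(0L, 0L, 6L))
})

test_that("FI-lab is invariant to lab row order", {
  co <- mini_cohort()
  perm <- co
  set.seed(4)
  perm$labs <- perm$labs[sample(nrow(perm$labs)), ]
  expect_equal(compute_scores(perm, n_fic_items = 5L)$fi_lab,
               compute_scores(co, n_fic_items = 5L)$fi_lab)
})

test_that("monotonicity: more abnormal results never lower FI-lab", {
  panel <- mini_panel()
  a <- panel$analytes
  lo <- ifelse(is.na(a$lower), a$lower_female, a$lower)
  hi <- ifelse(is.na(a$upper), a$upper_female, a$upper)
  mid <- (lo + hi) / 2
  prev <- -1
  for (k in 0:5) {
    vals <- mid
    if (k > 0) vals[seq_len(k)] <- hi[seq_len(k)] + 1
    s <- fi_lab_score(vals, a$analyte_id, "female", panel)$fi_lab
    expect_equal(s, k / 5)
    expect_gte(s, prev)
    prev <- s
  }
})

test_that("mean FI-lab converges to the per-analyte abnormal probability", {
  # law of large numbers at the generator's score level, no missingness
  cfg <- sim_config(n = 50000, seed = 21, abnormal_prob = 0.31,
                    missing_prob = 0)
  d <- simulate_scores(cfg)
  # SE of the cohort mean is sqrt(p(1-p)/35/n) ~ 0.00035; 0.002 is ~6 SE
  expect_lt(abs(mean(d$fi_lab) - 0.31), 0.002)
})
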