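# Shared fixtures, built in code.

# small 5-analyte panel (sodium sex-neutral, hemoglobin sex-specific)
mini_panel <- function() {
  reference_panel(data.frame(
    analyte_id = c("sodium", "potassium", "hemoglobin", "albumin", "crp"),
    units = c("mmol/L", "mmol/L", "g/dL", "g/dL", "mg/dL"),
    lower = c(135, 3.5, NA, 3.5, 0),
    upper = c(145, 5.0, NA, 5.0, 0.3),
    lower_male = c(NA, NA, 13.5, NA, NA),
    upper_male = c(NA, NA, 17.5, NA, NA),
    lower_female = c(NA, NA, 12.0, NA, NA),
    upper_female = c(NA, NA, 16.0, NA, NA)
  ), name = "mini-5")
}

# three-admission cohort over the mini panel
mini_admissions <- function() {
  data.frame(
    admission_id = c("A1", "A2", "A3"),
    age = c(72L, 65L, 88L),
    sex = c("male", "female", "male"),
    emergency = c(TRUE, FALSE, FALSE),
    history_of_falls = c(TRUE, FALSE, FALSE),
    mental_status = c(FALSE, FALSE, TRUE),
    vision = c(FALSE, FALSE, FALSE),
    toileting = c(FALSE, TRUE, FALSE),
    mobility = c(FALSE, FALSE, TRUE),
    antihypertensive = c(TRUE, TRUE, FALSE),
    antidiabetic = c(FALSE, FALSE, FALSE),
    antithrombotic = c(TRUE, FALSE, FALSE),
    sleep = c(FALSE, FALSE, TRUE),
    antipsychotic = c(FALSE, FALSE, FALSE),
    nsaid = c(FALSE, TRUE, FALSE),
    fell = c(FALSE, FALSE, TRUE),
    readmission_gap_days = c(NA_integer_, 45L, NA_integer_),
    stringsAsFactors = FALSE
  )
}

mini_labs <- function() {
  data.frame(
    admission_id = c("A1", "A1", "A1", "A1", "A2", "A2", "A2", "A2", "A3",
                     "A3", "A3", "A3"),
    analyte_id = c("sodium", "potassium", "hemoglobin", "albumin",
                   "sodium", "potassium", "hemoglobin", "crp",
                   "sodium", "potassium", "albumin", "crp"),
    value = c(130, 4.1, 14.2, 3.9,
              140, 5.5, 11.0, 0.1,
              142, 4.0, 2.9, 1.8),
    sequence = 1L,
    stringsAsFactors = FALSE
  )
}

mini_deficits <- function() {
  # 4 items per admission against a 5-item schema used in tests
  data.frame(
    admission_id = rep(c("A1", "A2", "A3"), each = 4),
    item_id = rep(c("fic01", "fic02", "fic03", "fic04"), 3),
    value = c(0, 0, 0.5, 0,
              0, 0, 0, 0,
              1, 0.5, 1, 0),
    stringsAsFactors = FALSE
  )
}

mini_cohort <- function() {
  fall_cohort(mini_admissions(), mini_labs(), mini_deficits(),
              icd10 = data.frame(admission_id = c("A3", "A3"),
                                 code = c("C78.0", "C18.9"),
                                 stringsAsFactors = FALSE),
              panel = mini_panel(), provenance = "test fixture")
}

# brute-force AUC: enumerate all (event, non-event) pairs with 0.5 tie credit
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  g <- outer(pos, neg, ">"); t <- outer(pos, neg, "==")
  (sum(g) + 0.5 * sum(t)) / (length(pos) * length(neg))
}

# score-level logistic data with known coefficients, for recovery tests
logistic_testdata <- function(n, beta0, beta, seed) {
  set.seed(seed)
  x <- matrix(rnorm(n * length(beta)), n)
  colnames(x) <- paste0("x", seq_along(beta))
  eta <- beta0 + drop(x %*% beta)
  d <- as.data.frame(x)
  d$fell <- runif(n) < plogis(eta)
  d
}
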