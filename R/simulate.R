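#' Configuration for the synthetic admission-cohort generator
#'
#' Defaults emulate the marginal structure of a geriatric acute-care cohort:
#' mean age 73 (SD 7.3, range 60-99), 63.5% male, 25.9% emergency admissions,
#' a per-analyte abnormality probability of 0.31 (so mean FI-lab is near
#' 0.31), a per-analyte missingness of 0.13 (mean measured ratio near 0.87),
#' STRATIFY item prevalences of 13.5/5.9/7.4/7.0/8.4%, clinical deficit
#' rates giving a mean clinical frailty index near 0.11, and a fall outcome
#' drawn from a logistic model with a marginal event rate of 2.9%.
#'
#' Outcome coefficients are log odds on the scale each score is reported on:
#' per year of age, male versus female, per STRATIFY point, and per 0.1 unit
#' of FI-lab / FI-clinical. When `target_rate` is set the intercept is solved
#' by bisection so the expected marginal event rate matches it; otherwise
#' `intercept` is used as given.
#'
#' @param n number of admissions (>= 1).
#' @param seed integer RNG seed; required, no implicit entropy.
#' @param age_mean,age_sd,age_min,age_max truncated-normal age distribution
#'   (years).
#' @param male_frac,emergency_frac marginal proportions.
#' @param abnormal_prob per-analyte probability of an out-of-range result
#'   (scalar, recycled over the panel).
#' @param abnormal_high_frac probability an abnormal result exceeds the upper
#'   rather than the lower limit.
#' @param missing_prob per-analyte probability a result is absent.
#' @param stratify_prev named prevalences for the five STRATIFY items.
#' @param med_prev named prevalences for the six medication categories.
#' @param fic_p1,fic_p05 per-item probabilities of a full (1) and partial
#'   (0.5) clinical deficit.
#' @param fic_missing per-item probability a clinical deficit item is
#'   unassessed.
#' @param condition_prev per-condition prevalence for Charlson comorbidities.
#' @param outcome named list of log-odds coefficients: `intercept`, `age`,
#'   `male`, `stratify`, `fi_lab` (per 0.1), `fi_clinical` (per 0.1).
#' @param target_rate marginal fall rate the intercept is calibrated to;
#'   `NULL` to use `outcome$intercept` directly.
#' @param latent_sd SD of an optional per-patient latent frailty factor added
#'   on the logit scale to every deficit and abnormality probability,
#'   inducing correlation between deficits. Default 0 (independence).
#' @param readmission_frac fraction of admissions marked as readmissions with
#'   a discharge-to-readmission gap drawn uniformly on 1-90 days.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n = 5984L, seed,
                       age_mean = 73, age_sd = 7.3, age_min = 60, age_max = 99,
                       male_frac = 0.635, emergency_frac = 0.259,
                       abnormal_prob = 0.31, abnormal_high_frac = 0.5,
                       missing_prob = 0.13,
                       stratify_prev = c(history_of_falls = 0.135,
                                         mental_status = 0.059,
                                         vision = 0.074,
                                         toileting = 0.070,
                                         mobility = 0.084),
                       med_prev = c(antihypertensive = 0.45,
                                    antidiabetic = 0.15,
                                    antithrombotic = 0.25,
                                    sleep = 0.20,
                                    antipsychotic = 0.05,
                                    nsaid = 0.10),
                       fic_p1 = 0.073, fic_p05 = 0.073, fic_missing = 0.05,
                       condition_prev = 0.08,
                       outcome = list(intercept = NA_real_,
                                      age = log(1.02),
                                      male = log(0.90),
                                      stratify = log(1.65),
                                      fi_lab = log(1.28),
                                      fi_clinical = log(1.25)),
                       target_rate = 0.029,
                       latent_sd = 0,
                       readmission_frac = 0) {
  if (missing(seed) || is.null(seed)) stop("sim_config requires an explicit seed")
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be at least 1")
  probs <- c(male_frac, emergency_frac, abnormal_prob, abnormal_high_frac,
             missing_prob, stratify_prev, med_prev, fic_p1, fic_p05,
             fic_missing, condition_prev, readmission_frac)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (fic_p1 + fic_p05 > 1) stop("fic_p1 + fic_p05 must not exceed 1")
  if (!is.null(target_rate) && !is.na(target_rate)) {
    if (target_rate <= 0 || target_rate >= 1) {
      stop("target marginal rate must lie strictly inside (0, 1)")
    }
  }
  need <- c("intercept", "age", "male", "stratify", "fi_lab", "fi_clinical")
  if (!all(need %in% names(outcome))) {
    stop("outcome model must name coefficients: ", paste(need, collapse = ", "))
  }
  structure(list(n = n, seed = as.integer(seed),
                 age_mean = age_mean, age_sd = age_sd,
                 age_min = age_min, age_max = age_max,
                 male_frac = male_frac, emergency_frac = emergency_frac,
                 abnormal_prob = abnormal_prob,
                 abnormal_high_frac = abnormal_high_frac,
                 missing_prob = missing_prob,
                 stratify_prev = stratify_prev, med_prev = med_prev,
                 fic_p1 = fic_p1, fic_p05 = fic_p05, fic_missing = fic_missing,
                 condition_prev = condition_prev,
                 outcome = outcome, target_rate = target_rate,
                 latent_sd = latent_sd, readmission_frac = readmission_frac),
            class = "sim_config")
}

#' Generate a synthetic admission cohort
#'
#' Draws a full [fall_cohort()] (demographics, long-format laboratory
#' results, clinical deficit items, medication flags, ICD-10 codes, and fall
#' outcomes) from a [sim_config()]. The generator is deterministic given the
#' config and its seed. Laboratory values are drawn inside the reference
#' interval with probability `1 - abnormal_prob`, otherwise uniformly on a
#' band beyond the violated limit of width half the interval; the magnitude
#' is irrelevant downstream because FI-lab counts each analyte as a binary
#' deficit. The fall outcome is Bernoulli on the logistic linear predictor
#' built from age, sex, the STRATIFY count, and the raw FI-lab / clinical
#' frailty fractions.
#'
#' @param config a [sim_config()].
#' @param panel the [reference_panel()] to simulate against.
#' @return a validated [fall_cohort()].
#' @export
simulate_cohort <- function(config, panel = default_panel()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n
  K <- panel$size
  ids <- sprintf("A%06d", seq_len(n))

  age <- draw_truncnorm(n, config$age_mean, config$age_sd,
                        config$age_min, config$age_max)
  sex <- ifelse(stats::runif(n) < config$male_frac, "male", "female")
  emergency <- stats::runif(n) < config$emergency_frac
  z <- if (config$latent_sd > 0) stats::rnorm(n, 0, config$latent_sd) else numeric(n)

  strat <- sapply(config$stratify_prev, function(p) {
    stats::runif(n) < stats::plogis(stats::qlogis(p) + z)
  })
  colnames(strat) <- stratify_item_names()
  meds <- sapply(config$med_prev, function(p) stats::runif(n) < p)
  colnames(meds) <- med_category_names()

  # laboratory block: n x K present / abnormal / value matrices
  a <- panel$analytes
  lo_m <- effective_limit(a, "lower", "male"); hi_m <- effective_limit(a, "upper", "male")
  lo_f <- effective_limit(a, "lower", "female"); hi_f <- effective_limit(a, "upper", "female")
  male <- sex == "male"
  lo <- outer(male, lo_m) ; lo[!male, ] <- matrix(lo_f, sum(!male), K, byrow = TRUE)
  lo[male, ] <- matrix(lo_m, sum(male), K, byrow = TRUE)
  hi <- lo; hi[male, ] <- matrix(hi_m, sum(male), K, byrow = TRUE)
  hi[!male, ] <- matrix(hi_f, sum(!male), K, byrow = TRUE)
  width <- hi - lo
  width[is.na(width)] <- pmax(abs(hi[is.na(width)]), abs(lo[is.na(width)]), 1,
                              na.rm = TRUE)

  p_ab <- rep_len(config$abnormal_prob, K)
  present <- matrix(stats::runif(n * K), n, K) >=
    matrix(rep_len(config$missing_prob, K), n, K, byrow = TRUE)
  p_ab_mat <- stats::plogis(matrix(stats::qlogis(pmin(pmax(p_ab, 1e-12), 1 - 1e-12)),
                                   n, K, byrow = TRUE) + z)
  abnormal <- matrix(stats::runif(n * K), n, K) < p_ab_mat
  go_high <- matrix(stats::runif(n * K), n, K) < config$abnormal_high_frac
  go_high[is.na(lo)] <- TRUE   # one-sided: only that limit can be violated
  go_high[is.na(hi)] <- FALSE
  u <- matrix(stats::runif(n * K), n, K)
  value <- lo + u * width                              # in-range draw
  value[is.na(value)] <- (hi - u * width)[is.na(value)]
  hi_draw <- hi + u * 0.5 * width
  lo_draw <- lo - u * 0.5 * width
  value[abnormal & go_high] <- hi_draw[abnormal & go_high]
  value[abnormal & !go_high] <- lo_draw[abnormal & !go_high]

  idx <- which(present, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  labs <- data.frame(admission_id = ids[idx[, 1]],
                     analyte_id = a$analyte_id[idx[, 2]],
                     value = value[idx],
                     sequence = 1L,
                     stringsAsFactors = FALSE)

  # clinical deficit block: n x 40 items
  n_items <- 40L
  fic_present <- matrix(stats::runif(n * n_items), n, n_items) >= config$fic_missing
  p1 <- stats::plogis(stats::qlogis(max(config$fic_p1, 1e-12)) + z)
  p05 <- stats::plogis(stats::qlogis(max(config$fic_p05, 1e-12)) + z)
  uf <- matrix(stats::runif(n * n_items), n, n_items)
  fic_value <- matrix(0, n, n_items)
  fic_value[uf < p1] <- 1
  fic_value[uf >= p1 & uf < p1 + p05] <- 0.5
  didx <- which(fic_present, arr.ind = TRUE)
  didx <- didx[order(didx[, 1], didx[, 2]), , drop = FALSE]
  deficits <- data.frame(admission_id = ids[didx[, 1]],
                         item_id = sprintf("fic%02d", didx[, 2]),
                         value = fic_value[didx],
                         stringsAsFactors = FALSE)

  # comorbidity codes: one representative code per simulated condition
  map <- default_cci_map()
  cond_hit <- matrix(stats::runif(n * length(map$condition)), n) < config$condition_prev
  cidx <- which(cond_hit, arr.ind = TRUE)
  cidx <- cidx[order(cidx[, 1], cidx[, 2]), , drop = FALSE]
  icd10 <- data.frame(admission_id = ids[cidx[, 1]],
                      code = vapply(map$prefixes[cidx[, 2]], `[[`, "", 1L),
                      stringsAsFactors = FALSE)

  barthel_full <- stats::runif(n) < 0.72
  barthel <- ifelse(barthel_full, 100,
                    pmax(0, 100 - 5 * (1 + stats::rpois(n, 4))))

  # outcome: logistic model on the derived scores
  measured <- rowSums(present)
  n_abn <- rowSums(abnormal & present)
  fi_lab_raw <- ifelse(measured > 0, n_abn / measured, mean(p_ab))
  fic_obs <- rowSums(fic_present)
  fi_clin_raw <- ifelse(fic_obs > 0,
                        rowSums(fic_value * fic_present) / fic_obs, 0)
  strat_score <- rowSums(strat)
  eta0 <- linear_predictor(config$outcome, age, male, strat_score,
                           fi_lab_raw, fi_clin_raw)
  intercept <- resolve_intercept(config, eta0)
  fell <- stats::runif(n) < stats::plogis(intercept + eta0)

  gap <- rep(NA_integer_, n)
  if (config$readmission_frac > 0) {
    is_re <- stats::runif(n) < config$readmission_frac
    gap[is_re] <- sample.int(90L, sum(is_re), replace = TRUE)
  }

  admissions <- data.frame(admission_id = ids, age = age, sex = sex,
                           emergency = emergency, stringsAsFactors = FALSE)
  admissions <- cbind(admissions, as.data.frame(strat), as.data.frame(meds))
  admissions$fell <- fell
  admissions$readmission_gap_days <- gap
  admissions$barthel <- as.numeric(barthel)

  fall_cohort(admissions, labs, deficits, icd10, panel = panel,
              provenance = sprintf("simulated (n=%d, seed=%d)", n, config$seed))
}

# linear predictor without intercept, on the reporting scales:
# age in years, male indicator, STRATIFY points, FI per 0.1 unit
linear_predictor <- function(coefs, age, male, stratify, fi_lab, fi_clinical) {
  coefs$age * age + coefs$male * male + coefs$stratify * stratify +
    coefs$fi_lab * (fi_lab / 0.1) + coefs$fi_clinical * (fi_clinical / 0.1)
}

resolve_intercept <- function(config, eta0) {
  tr <- config$target_rate
  if (is.null(tr) || is.na(tr)) {
    ic <- config$outcome$intercept
    if (is.null(ic) || is.na(ic)) {
      stop("outcome model needs either an intercept or a target marginal rate")
    }
    return(ic)
  }
  solve_intercept(eta0, tr)
}

# bisection on the intercept so that mean(plogis(c + eta0)) = target
solve_intercept <- function(eta0, target, tol = 1e-6) {
  f <- function(c0) mean(stats::plogis(c0 + eta0)) - target
  lo <- -40; hi <- 40
  if (f(lo) > 0 || f(hi) < 0) stop("target marginal rate unattainable")
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (abs(f(mid)) < tol * 1e-2 || (hi - lo) < 1e-12) break
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  mid
}

draw_truncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower - 0.5, mean, sd)
  phi <- stats::pnorm(upper + 0.5, mean, sd)
  x <- stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
  as.integer(pmin(pmax(round(x), lower), upper))
}

#' Generate score-level synthetic data
#'
#' A fast path through the same generating process that skips the long-format
#' laboratory and deficit tables: it draws the per-admission scores directly
#' (FI-lab as the abnormal fraction of a fully measured panel, the clinical
#' frailty index from the item model with no missingness, STRATIFY from its
#' item prevalences) and then the fall outcome from the logistic outcome
#' model. Used for large Monte-Carlo runs — population AUC estimation,
#' parameter-recovery and size simulations — where materializing millions of
#' laboratory rows adds nothing.
#'
#' @param config a [sim_config()] (its `missing_prob` is ignored: the panel
#'   is treated as fully measured).
#' @param n number of admissions, default `config$n`.
#' @param panel_size analyte count used for the FI-lab binomial, default 35.
#' @return data.frame with `age`, `sex`, `stratify`, `fi_lab`, `fi_clinical`,
#'   `eta` (the realized linear predictor) and `fell`.
#' @export
simulate_scores <- function(config, n = config$n, panel_size = 35L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  age <- draw_truncnorm(n, config$age_mean, config$age_sd,
                        config$age_min, config$age_max)
  male <- stats::runif(n) < config$male_frac
  z <- if (config$latent_sd > 0) stats::rnorm(n, 0, config$latent_sd) else numeric(n)
  strat_score <- rowSums(sapply(config$stratify_prev, function(p) {
    stats::runif(n) < stats::plogis(stats::qlogis(p) + z)
  }))
  p_ab <- rep_len(config$abnormal_prob, panel_size)
  if (config$latent_sd > 0) {
    abn <- sapply(p_ab, function(p) {
      stats::runif(n) < stats::plogis(stats::qlogis(min(max(p, 1e-12), 1 - 1e-12)) + z)
    })
    fi_lab <- rowSums(abn) / panel_size
  } else {
    fi_lab <- stats::rbinom(n, panel_size, p_ab[1]) / panel_size
  }
  n_items <- 40L
  u <- matrix(stats::runif(n * n_items), n, n_items)
  p1 <- stats::plogis(stats::qlogis(max(config$fic_p1, 1e-12)) + z)
  p05 <- stats::plogis(stats::qlogis(max(config$fic_p05, 1e-12)) + z)
  fi_clinical <- rowSums((u < p1) * 1 + (u >= p1 & u < p1 + p05) * 0.5) / n_items
  eta0 <- linear_predictor(config$outcome, age, male, strat_score,
                           fi_lab, fi_clinical)
  intercept <- resolve_intercept(config, eta0)
  eta <- intercept + eta0
  data.frame(age = age, sex = ifelse(male, "male", "female"),
             stratify = as.integer(strat_score), fi_lab = fi_lab,
             fi_clinical = fi_clinical, eta = eta,
             fell = stats::runif(n) < stats::plogis(eta),
             stringsAsFactors = FALSE)
}

#' Population AUROC of a score under the generating process
#'
#' Estimates, by large-sample Monte Carlo, the probability that a randomly
#' chosen faller receives a higher value of the named score than a randomly
#' chosen non-faller, under the configured generating process. The standard
#' error is the DeLong estimate on the Monte-Carlo sample.
#'
#' @param config a [sim_config()].
#' @param score one of `"linear_predictor"`, `"fi_lab"`, `"fi_clinical"`,
#'   `"stratify"`, `"age"`.
#' @param n Monte-Carlo sample size (default 1e6).
#' @return list with `auc`, `se`, `n`.
#' @export
true_auc <- function(config, score = "linear_predictor", n = 1e6) {
  stopifnot(inherits(config, "sim_config"))
  d <- simulate_scores(config, n = n)
  s <- switch(score,
              linear_predictor = d$eta,
              fi_lab = d$fi_lab,
              fi_clinical = d$fi_clinical,
              stratify = d$stratify,
              age = d$age,
              stop("unknown score name: ", score))
  r <- roc_auc(s, d$fell)
  list(auc = r$auc, se = r$se, n = n)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: n=%d seed=%d | age %g (%g), male %.1f%%\n",
              x$n, x$seed, x$age_mean, x$age_sd, 100 * x$male_frac))
  cat(sprintf("  abnormal prob %.3g, missingness %.3g, target fall rate %s\n",
              mean(x$abnormal_prob), mean(x$missing_prob),
              if (is.null(x$target_rate) || is.na(x$target_rate)) "(intercept fixed)"
              else format(x$target_rate)))
  invisible(x)
}
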