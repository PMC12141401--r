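study_fixture_config <- function(seed = 3, n = 900, B = 50) {
  study_config(input = sim_config(n = n, seed = 101),
               models = c("m1", "m2", "m5"),
               comparisons = list(c("m1", "m2"), c("m1", "m5")),
               B = B, seed = seed, validate_models = "m1",
               cutoff_scan = TRUE)
}

test_that("descriptive summaries handle constants and dual reporting", {
  sc <- compute_scores(simulate_cohort(sim_config(n = 300, seed = 43)))
  de <- descriptives(sc)
  expect_true(all(c("variable", "stat", "value", "label") %in% names(de)))
  # STRATIFY and Barthel are reported both ways
  expect_equal(sum(de$variable == "stratify"), 2L)
  expect_equal(sum(de$variable == "barthel"), 2L)

  const <- sc; const$stratify <- 2L
  dc <- descriptives(const)
  expect_equal(dc$value2[dc$variable == "stratify" & dc$stat == "mean_sd"], 0)
  expect_equal(dc$value2[dc$variable == "stratify" & dc$stat == "median_iqr"], 0)
})

test_that("Spearman correlation: self-correlation 1, tie-corrected fixture value", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(spearman_rho(x, x)$rho, 1.0)
  # 6-point fixture with one tie pair, against the midrank Pearson formula
  y <- c(2, 2, 1, 4, 6, 5)
  rho_direct <- cor(rank(x), rank(y))
  sp <- spearman_rho(x, y)
  expect_equal(sp$rho, rho_direct)
  expect_equal(sp$n, 6L)
  expect_lt(sp$p, 0.2)
  expect_equal(spearman_rho(x, -x)$rho, -1.0)
})

test_that("run_study produces a coherent report bundle", {
  res <- run_study(study_fixture_config())
  expect_false(res$partial)
  expect_equal(res$flow$included, nrow(res$scores))
  # fall-rate cell consistency
  rate_row <- res$descriptives[res$descriptives$variable == "in_hospital_falls", ]
  expect_equal(rate_row$value, sum(res$scores$fell))
  expect_equal(rate_row$value2, 100 * mean(res$scores$fell))

  cmp <- res$comparisons
  # delta AUC sign agrees with the printed AUC difference, row by row
  expect_equal(sign(cmp$delta_auc), sign(cmp$auc_new - cmp$auc_ref))
  # NRI components sum to NRI in every emitted (non-suppressed) row
  m2row <- cmp[cmp$model == "m2", ]
  fell <- res$scores$fell   # analysis set equals the scored set here
  nri_parts <- continuous_nri(res$suite$fits$m1$fitted,
                              res$suite$fits$m2$fitted, fell)
  expect_equal(nri_parts$estimate, nri_parts$events + nri_parts$nonevents)
  expect_equal(m2row$nri, nri_parts$estimate)
  # the FI-lab + FI-clinical model omits STRATIFY: NRI/IDI suppressed
  m5row <- cmp[cmp$model == "m5", ]
  expect_true(is.na(m5row$nri) && is.na(m5row$idi))
  expect_false(is.na(m5row$delong_p))

  expect_named(res$validation, "m1")
  expect_equal(res$validation$m1$corrected_c,
               res$validation$m1$apparent_c - res$validation$m1$optimism)
})

test_that("the six-item STRATIFY model keeps its reclassification cells", {
  cfg <- study_config(input = sim_config(n = 900, seed = 103),
                      models = c("m1", "m3"),
                      comparisons = list(c("m1", "m3")),
                      B = 50, seed = 4, validate_models = character(0),
                      cutoff_scan = FALSE)
  res <- run_study(cfg)
  expect_false(is.na(res$comparisons$nri[1]))
  expect_false(is.na(res$comparisons$idi[1]))
})

test_that("rerunning with the same config and seed is byte-identical", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  run_study(study_fixture_config(), out_dir = dir1)
  run_study(study_fixture_config(), out_dir = dir2)
  files <- sort(list.files(dir1))
  expect_true(length(files) >= 7)
  expect_identical(files, sort(list.files(dir2)))
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))),
                     info = f)
  }
})

test_that("a failing stage marks the bundle partial with a diagnostic", {
  cfg <- study_config(input = "no/such/dir", B = 50, seed = 1)
  expect_warning(res <- run_study(cfg), "partial")
  expect_true(res$partial)
  expect_match(res$diagnostics$input, "not found")
})

test_that("study config validates comparisons against the model list", {
  expect_error(study_config(input = sim_config(n = 10, seed = 1),
                            models = c("m1", "m2"),
                            comparisons = list(c("m1", "m6")), seed = 1),
               "drawn from 'models'")
  expect_error(study_config(input = sim_config(n = 10, seed = 1)), "seed")
})

test_that("the command-line front end simulates and scores a bundle", {
  cli <- system.file("cli", "frailtyfalls.R", package = "frailtyfalls")
  skip_if(cli == "", "CLI script not installed")
  dir <- withr::local_tempdir()
  cfg_path <- file.path(dir, "sim.yaml")
  writeLines(c("n: 120", "seed: 7"), cfg_path)
  out_bundle <- file.path(dir, "bundle")
  env <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  status <- system2("Rscript", c(cli, "simulate", "--config", cfg_path,
                                 "--out", out_bundle),
                    env = env, stdout = FALSE, stderr = FALSE)
  expect_equal(status, 0L)
  expect_true(file.exists(file.path(out_bundle, "admissions.csv")))
  scores_csv <- file.path(dir, "scores.csv")
  status2 <- system2("Rscript", c(cli, "score", "--in", out_bundle,
                                  "--out", scores_csv),
                     env = env, stdout = FALSE, stderr = FALSE)
  expect_equal(status2, 0L)
  sc <- read.csv(scores_csv)
  expect_true(all(c("fi_lab", "stratify", "cci") %in% names(sc)))
})
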