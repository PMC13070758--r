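test_that("generation is deterministic for a fixed seed", {
  a <- generate_cohort(simulation_config(seed = 1))
  b <- generate_cohort(simulation_config(seed = 1))
  expect_identical(a, b)
  c_ <- generate_cohort(simulation_config(seed = 2))
  expect_false(identical(a$clinical, c_$clinical))
})

test_that("counts respect the library size and compositions close to 1", {
  coh <- generate_cohort(simulation_config(n_participants = 40, seed = 3))
  libs <- rowSums(coh$abundances$values)
  rng <- coh$truth$config$library_size_range
  expect_true(all(libs >= rng[1] & libs <= rng[2]))
  expect_true(all(coh$abundances$values ==
                    round(coh$abundances$values)))
  rel <- to_relative(coh$abundances)
  expect_true(all(abs(rowSums(rel$values) - 1) < 1e-9))
  expect_true(all(abs(rowSums(coh$truth$true_relative) - 1) < 1e-9))
})

test_that("null outcome coefficients give 50% prevalence", {
  cfg <- simulation_config(
    n_participants = 2000,
    outcome_coefficients = c(intercept = 0, age = 0, bmi = 0,
                             prior_gdm = 0, fpg = 0, micro_balance = 0),
    target_prevalence = NA, seed = 4)
  coh <- generate_cohort(cfg)
  # binomial error at n = 2000: 3 * sqrt(0.25/2000) ~ 0.034
  expect_equal(mean(coh$clinical$gdm), 0.5, tolerance = 0.04)
})

test_that("intercept solving hits the target prevalence in expectation", {
  coh <- generate_cohort(simulation_config(n_participants = 3000, seed = 5))
  expect_equal(mean(coh$truth$probabilities), 22 / 98, tolerance = 1e-6)
  expect_equal(mean(coh$clinical$gdm), 22 / 98, tolerance = 0.03)
})

test_that("structural-zero rates surface as taxon prevalence", {
  cfg <- simulation_config(n_participants = 3000, seed = 6)
  coh <- generate_cohort(cfg)
  zi <- cfg$zero_inflation
  # on the true compositions the prevalence is exactly 1 - zero_inflation
  prev_true <- colMeans(coh$truth$true_relative > 0)
  for (j in seq_along(zi)) {
    expect_lt(abs(prev_true[j] - (1 - zi[j])), 0.04)
  }
  # on sampled counts, abundant taxa show the same prevalence
  prev_counts <- colMeans(coh$abundances$values > 0)
  abundant <- which(cfg$dirichlet_concentration > 1)
  for (j in abundant) {
    expect_lt(abs(prev_counts[j] - (1 - zi[j])), 0.05)
  }
})

test_that("a planted balance effect is visible to a micro-only model", {
  coh <- generate_cohort(simulation_config(n_participants = 2000, seed = 9))
  X <- build_design(coh$clinical, model_spec("micro_only"),
                    coh$truth$balance)
  f <- fit_logistic(X, coh$clinical$gdm)
  auc <- auc_mann_whitney(f$fitted_probabilities, coh$clinical$gdm)
  expect_gt(auc, 0.6)
})

test_that("OGTT shift raises post-load glucose in outcome-positive women", {
  coh <- generate_cohort(simulation_config(n_participants = 3000, seed = 10))
  cl <- coh$clinical
  expect_equal(mean(cl$pg1h[cl$gdm == 1]) - mean(cl$pg1h[cl$gdm == 0]),
               1.8, tolerance = 0.25)
  # the IADPSG classifier is exercised in both directions
  flags <- classify_gdm(ogtt_record(cl$fpg, cl$pg1h, cl$pg2h))
  expect_true(any(flags) && any(!flags))
  expect_gt(mean(flags[cl$gdm == 1]), mean(flags[cl$gdm == 0]))
})

test_that("cohorts round-trip through CSV/TSV at full precision", {
  coh <- generate_cohort(simulation_config(n_participants = 20, seed = 11))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(back$clinical, coh$clinical)
  expect_equal(back$abundances$values, coh$abundances$values)
  expect_identical(back$abundances$taxa, coh$abundances$taxa)
  expect_equal(back$truth$coefficients, coh$truth$coefficients)
})

test_that("malformed cohort files are rejected with useful messages", {
  coh <- generate_cohort(simulation_config(n_participants = 10, seed = 12))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  # duplicated sample id in the abundance TSV
  ab <- readLines(file.path(dir, "abundance.tsv"))
  writeLines(c(ab, ab[2]), file.path(dir, "abundance.tsv"))
  expect_error(read_cohort(dir), "duplicated sample id")
  # ragged line reported with its line number
  write_cohort(coh, dir)
  ab <- readLines(file.path(dir, "abundance.tsv"))
  ab[4] <- paste(ab[4], "extra", sep = "\t")
  writeLines(ab, file.path(dir, "abundance.tsv"))
  expect_error(read_cohort(dir), "line 4")
  # missing outcome column named in the error
  write_cohort(coh, dir)
  cl <- read.csv(file.path(dir, "clinical.csv"))
  cl$gdm <- NULL
  write.csv(cl, file.path(dir, "clinical.csv"), row.names = FALSE)
  expect_error(read_cohort(dir), "gdm")
})

test_that("invalid configurations name the offending field", {
  expect_error(simulation_config(n_participants = 1), "n_participants")
  expect_error(simulation_config(taxon_names = c("g__A", "g__A")),
               "taxon_names")
  expect_error(simulation_config(taxon_names = c("g__A", "g__B")),
               "Bifidobacterium")
  expect_error(simulation_config(prior_gdm_prevalence = 2),
               "prior_gdm_prevalence")
  expect_error(simulation_config(zero_inflation = rep(-0.1, 29)),
               "zero_inflation")
  expect_error(simulation_config(dirichlet_concentration = rep(0, 29)),
               "dirichlet_concentration")
  expect_error(simulation_config(library_size_range = c(0, 10)),
               "library_size_range")
  expect_error(simulation_config(
    outcome_coefficients = c(intercept = 0, age = 1)),
    "outcome_coefficients")
})
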