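# Harness structure and determinism checks run at deliberately small sizes
# with a fixed penalty so each block stays fast; the statistical patterns
# the harnesses were built to measure are asserted in test-acceptance.R.

test_that("class-bias sweep covers its grid with both compositions and is reproducible", {
  cfg <- sim_config(n_sites = 60, n_samples = 600, seed = 1)
  res <- run_class_bias_sweep(cfg, proportions = c(0.1, 0.6),
                              n_replicates = 2, seed = 9, lambda = 0.05)
  expect_identical(nrow(res), 2L * 2L * 2L)
  expect_setequal(unique(res$composition), c("mixed", "biased"))
  tab <- table(res$bias_proportion, res$composition)
  expect_true(all(tab == 2))
  res2 <- run_class_bias_sweep(cfg, proportions = c(0.1, 0.6),
                               n_replicates = 2, seed = 9, lambda = 0.05)
  expect_identical(res, res2)
  expect_error(
    run_class_bias_sweep(sim_config(n_samples = 300), proportions = 0.5,
                         n_replicates = 1),
    "budget")
})

test_that("age scenarios produce one row per scenario and replicate with band-true splits", {
  cfg <- sim_config(n_sites = 60, n_samples = 600, clip_mode = "clip01",
                    seed = 2)
  res <- run_age_scenarios(cfg, n_replicates = 2, lambda = 0.05)
  expect_identical(nrow(res), 4L * 2L)
  expect_setequal(unique(res$scenario),
                  c("unbiased", "young_biased", "old_biased", "prime_age"))
  expect_true(all(is.finite(res$mae)))
})

test_that("ageing-error grid is a complete factorial with training on reported ages", {
  cfg <- sim_config(n_sites = 40, clip_mode = "clip01", seed = 3)
  res <- run_error_by_n_grid(cfg, sd_grid = c(0, 3), n_grid = c(60, 120),
                             n_replicates = 2, lambda = 0.05)
  expect_identical(nrow(res), 2L * 2L * 2L)
  tab <- table(res$age_error_sd, res$n_total)
  expect_true(all(tab == 2))
})

test_that("overlap sweep controls the class share of the training set", {
  design <- cohort_design(list(tissue = c(blood = 0.5, skin = 0.5)))
  sim <- simulate_structured_cohort(sim_config(n_sites = 50,
                                               n_samples = 200, seed = 4),
                                    design)
  res <- run_overlap_sweep(sim$betas, sim$meta, "tissue", "blood",
                           overlap_grid = c(0, 1), n_clocks = 2,
                           train_n = 40, test_n = 20, seed = 6,
                           lambda = 0.05)
  expect_identical(nrow(res), 4L)
  expect_setequal(unique(res$overlap), c(0, 1))
  expect_error(
    run_overlap_sweep(sim$betas, sim$meta, "tissue", "muscle",
                      overlap_grid = 0.5, n_clocks = 1),
    "not present")
  expect_error(
    run_overlap_sweep(sim$betas, sim$meta, "tissue", "blood",
                      overlap_grid = 0.5, n_clocks = 1, test_n = 1000),
    "need >=")
})

test_that("feature-selection sweep arms coincide with nothing to remove and fail gracefully at full removal", {
  cfg <- sim_config(n_sites = 60, n_samples = 600, seed = 5)
  res0 <- run_feature_selection_sweep(cfg, removal_grid = 0,
                                      n_replicates = 2, lambda = 0.05)
  ret <- res0[res0$arm == "retained", ]
  sel <- res0[res0$arm == "selected", ]
  expect_equal(ret$mae, sel$mae)
  expect_equal(ret$r_squared, sel$r_squared)

  res1 <- run_feature_selection_sweep(cfg, removal_grid = 1,
                                      n_replicates = 1, lambda = 0.05)
  sel1 <- res1[res1$arm == "selected", ]
  expect_identical(sel1$status, "failed")
  expect_identical(sel1$n_sites_used, 0L)
  expect_true(is.na(sel1$mae))
  expect_identical(res1[res1$arm == "retained", ]$status, "ok")
})

test_that("selection ladder records surviving site counts per rung", {
  design <- cohort_design(list(tissue = c(blood = 0.5, skin = 0.5),
                               sex = c(F = 0.5, M = 0.5)))
  sim <- simulate_structured_cohort(sim_config(n_sites = 80,
                                               n_samples = 200, seed = 6),
                                    design)
  keep <- colnames(sim$betas)[1:60]
  res <- run_selection_ladder(sim$betas, sim$meta, keep, n_clocks = 2,
                              p_threshold = 0.05, seed = 7, lambda = 0.05)
  expect_identical(nrow(res), 6L * 2L)
  counts <- tapply(res$n_sites_used, res$rung, unique)
  expect_identical(counts[["no_fs"]], 80L)
  expect_identical(counts[["alignment"]], 60L)
  expect_lte(counts[["full"]], counts[["age_tissue_sex"]])
  expect_lte(counts[["age_tissue_sex"]], counts[["age_sex"]])
})

test_that("validation comparison emits paired rows and rejects empty hold-outs", {
  sim <- simulate_linear_betas(sim_config(n_sites = 30, n_samples = 60,
                                          seed = 7))
  res <- run_validation_comparison(sim$betas, sim$meta, n_repetitions = 2,
                                   subset_n = 40, train_n = 25,
                                   seed = 8, lambda = 0.05)
  expect_identical(nrow(res), 4L)
  expect_identical(sum(res$scheme == "holdout"), 2L)
  expect_identical(sum(res$scheme == "loo"), 2L)
  expect_setequal(res$replicate[res$scheme == "loo"],
                  res$replicate[res$scheme == "holdout"])
  expect_error(
    run_validation_comparison(sim$betas, sim$meta, n_repetitions = 1,
                              subset_n = 40, train_n = 40),
    "hold-out")
})
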