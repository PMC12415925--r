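test_that("linear simulator is seed-deterministic and matches its closed form", {
  cfg <- sim_config(n_sites = 40, n_samples = 31, seed = 5)
  a <- simulate_linear_betas(cfg)
  b <- simulate_linear_betas(cfg)
  expect_identical(a$betas, b$betas)
  expect_identical(a$meta, b$meta)

  # noise-free values are exactly slope * age (e.g. slope 0.1 at age 10 -> 1)
  cfg0 <- sim_config(n_sites = 40, n_samples = 31, noise_sd = 0, seed = 5)
  s0 <- simulate_linear_betas(cfg0)
  expected <- outer(s0$meta$age_true, s0$site_params$slope)
  dimnames(expected) <- dimnames(s0$betas)
  expect_equal(s0$betas, expected, tolerance = 0)

  # degenerate null: all slopes zero, no noise -> all-zero matrix
  null0 <- simulate_linear_betas(sim_config(n_sites = 10, n_samples = 12,
                                            slope_range = c(0, 0),
                                            noise_sd = 0, seed = 1))
  expect_true(all(null0$betas == 0))

  expect_error(sim_config(n_sites = 0), "positive")
  expect_error(sim_config(n_samples = -3), "positive")
  expect_error(sim_config(age_min = 30, age_max = 0), "less than")
})

test_that("per-site regression slopes recover the drawn slopes", {
  sim <- simulate_linear_betas(sim_config(n_sites = 50, n_samples = 300,
                                          seed = 42))
  age <- sim$meta$age_true
  slope_hat <- as.numeric(crossprod(age - mean(age), sim$betas) /
                            sum((age - mean(age))^2))
  # sampling error of each OLS slope is ~0.0033 here; 0.02 is ~6 sigma
  expect_lt(max(abs(slope_hat - sim$site_params$slope)), 0.02)
})

test_that("class-bias injection flags round(prop * n_sites) sites and is a no-op at zero settings", {
  sim <- simulate_linear_betas(sim_config(n_sites = 500, n_samples = 20,
                                          seed = 2))
  meta <- sim$meta
  meta$class <- rep(c("biased", "unbiased"), length.out = nrow(meta))

  inj <- inject_class_bias(sim$betas, meta, 0.05, 0.5, "biased", seed = 9)
  expect_length(inj$biased_sites, 25)
  expect_true(all(inj$biased_sites %in% colnames(sim$betas)))
  # only biased-class rows at flagged sites change
  changed <- which(inj$betas != sim$betas, arr.ind = TRUE)
  expect_true(all(rownames(sim$betas)[changed[, 1]] %in%
                    meta$sample_id[meta$class == "biased"]))
  expect_true(all(colnames(sim$betas)[changed[, 2]] %in% inj$biased_sites))

  expect_identical(
    inject_class_bias(sim$betas, meta, 0, 0.5, "biased", seed = 9)$betas,
    sim$betas)
  expect_identical(
    inject_class_bias(sim$betas, meta, 0.5, 0, "biased", seed = 9)$betas,
    sim$betas)
  expect_error(inject_class_bias(sim$betas, meta, 0.5, 0.5, "nope"),
               "not present")
})

test_that("non-linear simulator matches age^exponent and rejects negative ages", {
  cfg0 <- sim_config(n_sites = 30, n_samples = 31, noise_sd = 0, seed = 3)
  s0 <- simulate_nonlinear_betas(cfg0)
  expected <- outer(s0$meta$age_true, s0$site_params$exponent, `^`)
  dimnames(expected) <- dimnames(s0$betas)
  expect_equal(s0$betas, expected, tolerance = 0)
  # age 0 gives exactly 0, and noise-free trajectories increase with age
  expect_true(all(s0$betas[1, ] == 0))
  expect_true(all(diff(s0$betas[, 1]) > 0))
  expect_true(all(apply(s0$betas[-1, ], 2, function(x) all(diff(x) > 0))))

  expect_error(
    simulate_nonlinear_betas(sim_config(age_min = -5, age_max = 30)),
    "non-negative")
  # the conventional noise level for this model
  s <- simulate_nonlinear_betas(sim_config(n_sites = 5, n_samples = 6))
  expect_equal(s$config$noise_sd, 0.8)
})

test_that("ageing error perturbs reported ages only, with the normal-law mean deviation", {
  sim <- simulate_linear_betas(sim_config(n_sites = 2, n_samples = 10000,
                                          seed = 8))
  m0 <- inject_age_error(sim$meta, 0, seed = 1)
  expect_identical(m0$age_reported, m0$age_true)

  m3 <- inject_age_error(sim$meta, 3, seed = 1)
  expect_identical(m3$age_true, sim$meta$age_true)
  # E|N(0,3)| = 3 * sqrt(2/pi) = 2.3936; MC standard error here ~0.018
  expect_equal(mean(abs(m3$age_reported - m3$age_true)), 3 * sqrt(2 / pi),
               tolerance = 0.03)

  mt <- inject_age_error(sim$meta, 10, seed = 1, truncate_at_zero = TRUE)
  expect_gte(min(mt$age_reported), 0)
  expect_error(inject_age_error(sim$meta, -1), ">= 0")
})

test_that("structured cohorts hit design proportions within rounding and reduce to the plain simulator", {
  design <- cohort_design(list(tissue = c(blood = 0.43, skin = 0.57),
                               sex = c(F = 0.5, M = 0.5)))
  sim <- simulate_structured_cohort(sim_config(n_sites = 20,
                                               n_samples = 235, seed = 6),
                                    design)
  counts <- table(sim$meta$tissue)
  expect_true(abs(counts[["blood"]] - 101) <= 1)
  expect_true(abs(counts[["skin"]] - 134) <= 1)

  # one level per factor, no effects: methylation identical to the plain
  # linear simulator
  one <- simulate_structured_cohort(
    sim_config(n_sites = 20, n_samples = 50, seed = 6),
    cohort_design(list(tissue = c(blood = 1))))
  plain <- simulate_linear_betas(sim_config(n_sites = 20, n_samples = 50,
                                            seed = 6))
  expect_identical(one$betas, plain$betas)

  expect_error(cohort_design(list(tissue = c(blood = 0.6, skin = 0.6))),
               "sum to 1")
  expect_error(
    simulate_structured_cohort(
      sim_config(n_sites = 10, n_samples = 20),
      cohort_design(list(tissue = c(blood = 0.5, skin = 0.5)),
                    effects = list(list(factor = "tissue", level = "blood",
                                        sites = 5:15, shift = 1)))),
    "outside")
})

test_that("planted class effects shift the designated sites for the designated class only", {
  design <- cohort_design(
    list(tissue = c(blood = 0.5, skin = 0.5)),
    effects = list(list(factor = "tissue", level = "blood",
                        sites = 1:10, shift = 0.3)))
  cfg <- sim_config(n_sites = 30, n_samples = 100, noise_sd = 0, seed = 4)
  sim <- simulate_structured_cohort(cfg, design)
  plain <- simulate_linear_betas(cfg)
  blood <- sim$meta$tissue == "blood"
  expect_equal(sim$betas[blood, 1:10], plain$betas[blood, 1:10] + 0.3,
               tolerance = 0)
  expect_identical(sim$betas[!blood, ], plain$betas[!blood, ])
  expect_identical(sim$betas[, 11:30], plain$betas[, 11:30])
  expect_identical(sim$effect_sites[[1]]$sites, colnames(sim$betas)[1:10])
})

test_that("clip01 mode bounds every value in [0, 1] for both models", {
  for (gen in list(simulate_linear_betas, simulate_nonlinear_betas)) {
    s <- gen(sim_config(n_sites = 50, n_samples = 60, noise_sd = 0.8,
                        clip_mode = "clip01", seed = 10))
    expect_true(all(s$betas >= 0 & s$betas <= 1))
  }
})
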