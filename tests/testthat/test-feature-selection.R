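test_that("alignment filter keeps the keep-list intersection and accounts for every site", {
  X <- tiny_betas(6, 10)
  full <- filter_by_alignment(X, colnames(X))
  expect_identical(full$betas, X)
  expect_identical(nrow(full$report$excluded), 0L)

  keep <- colnames(X)[1:9]
  res <- filter_by_alignment(X, keep)
  expect_identical(colnames(res$betas), keep)
  expect_identical(res$report$excluded$site_id, colnames(X)[10])
  expect_identical(res$report$excluded$reason, "alignment")
  # exhaustive and disjoint accounting
  expect_setequal(c(res$report$retained_site_ids,
                    res$report$excluded$site_id), colnames(X))

  expect_error(filter_by_alignment(X, c("zz1", "zz2")), "nothing to train")
  expect_error(filter_by_alignment(X, character(0)), "empty")
})

test_that("sitewise models agree exactly with per-site lm() fits", {
  design <- cohort_design(list(tissue = c(blood = 0.5, skin = 0.5),
                               sex = c(F = 0.5, M = 0.5)))
  sim <- simulate_structured_cohort(sim_config(n_sites = 8, n_samples = 60,
                                               seed = 17), design)
  stats <- fit_sitewise_models(sim$betas, sim$meta, c("tissue", "sex"))
  for (j in seq_len(ncol(sim$betas))) {
    df <- data.frame(y = sim$betas[, j], age_true = sim$meta$age_true,
                     tissue = sim$meta$tissue, sex = sim$meta$sex)
    fit <- lm(y ~ age_true + tissue + sex, data = df)
    sm <- summary(fit)
    expect_equal(stats$age_slope[j], unname(coef(fit)["age_true"]),
                 tolerance = 1e-10)
    expect_equal(stats$age_p[j], sm$coefficients["age_true", 4],
                 tolerance = 1e-10)
    dr <- drop1(fit, ~ tissue + sex, test = "F")
    expect_equal(stats$tissue_p[j], dr["tissue", "Pr(>F)"],
                 tolerance = 1e-10)
    expect_equal(stats$sex_p[j], dr["sex", "Pr(>F)"], tolerance = 1e-10)
  }
})

test_that("planted class-effect sites dominate the class p-value ranking", {
  design <- cohort_design(
    list(tissue = c(blood = 0.5, skin = 0.5)),
    effects = list(list(factor = "tissue", level = "blood",
                        sites = 1:50, shift = 0.3)))
  sim <- simulate_structured_cohort(sim_config(n_sites = 400,
                                               n_samples = 400, seed = 23),
                                    design)
  stats <- fit_sitewise_models(sim$betas, sim$meta, "tissue")
  planted <- stats$site_id %in% sim$effect_sites[[1]]$sites
  # planted sites should occupy essentially all of the lowest ranks
  top50 <- order(stats$tissue_p)[1:50]
  expect_gte(sum(planted[top50]), 45)
})

test_that("single-level factors are dropped with a warning, keeping the age term", {
  X <- tiny_betas(30, 4)
  meta <- tiny_meta(X)
  meta$tissue <- "blood"
  meta$sex <- rep(c("F", "M"), 15)
  expect_warning(
    stats <- fit_sitewise_models(X, meta, c("tissue", "sex")),
    "single level")
  expect_identical(attr(stats, "factors"), "sex")
  expect_true(all(c("age_slope", "age_p", "sex_p") %in% names(stats)))
  expect_false("tissue_p" %in% names(stats))
})

test_that("class-bias exclusion respects its threshold at both extremes", {
  design <- cohort_design(list(sex = c(F = 0.5, M = 0.5)))
  sim <- simulate_structured_cohort(sim_config(n_sites = 50,
                                               n_samples = 80, seed = 3),
                                    design)
  stats <- fit_sitewise_models(sim$betas, sim$meta, "sex")
  expect_length(
    exclude_class_biased_sites(stats, 0)$excluded$site_id, 0)
  expect_length(
    exclude_class_biased_sites(stats, 1)$retained_site_ids, 0)
  rep_mid <- exclude_class_biased_sites(stats, 0.05)
  expect_setequal(c(rep_mid$retained_site_ids, rep_mid$excluded$site_id),
                  stats$site_id)
})

test_that("age-association filter requires a significant slope in every group", {
  ch <- sexed_cohort()
  rep <- retain_age_associated_sites(ch$betas, ch$meta, "sex",
                                     p_threshold = 0.001)
  expect_identical(rep$retained_site_ids, "cg_shared")
  expect_setequal(rep$excluded$site_id, c("cg_female", "cg_noise"))
  expect_identical(unique(rep$excluded$reason), "no_age_signal")

  small <- ch$meta[1:5, ]
  small$sex <- c("F", "F", "F", "F", "M")  # M has 1 sample
  expect_error(
    retain_age_associated_sites(ch$betas[1:5, ], small, "sex"), ">= 3")
})

test_that("variance filter ranks by sample variance with deterministic ties", {
  X <- cbind(a = c(1, 1, 1, 1), b = c(0, 2, 4, 6), c = c(0, 1, 2, 3))
  rownames(X) <- paste0("s", 1:4)
  # hand-computed variances: a = 0, b = 20/3, c = 5/3
  all_kept <- variance_filter(X, top_k = 3)
  expect_identical(all_kept$retained_site_ids, c("a", "b", "c"))
  top2 <- variance_filter(X, top_k = 2)
  expect_setequal(top2$retained_site_ids, c("b", "c"))
  expect_identical(top2$excluded$site_id, "a")

  # exact tie broken by site ID order
  Xt <- cbind(z = c(0, 1, 2, 3), m = c(3, 2, 1, 0), a = c(9, 9, 9, 9))
  rownames(Xt) <- paste0("s", 1:4)
  one <- variance_filter(Xt, top_k = 1)
  expect_identical(one$retained_site_ids, "m")

  expect_error(variance_filter(X, top_k = 9), "exceeds")
  expect_error(variance_filter(X), "exactly one")
  expect_error(variance_filter(X, top_k = 1, min_variance = 1),
               "exactly one")
  expect_identical(variance_filter(X, min_variance = 1)$retained_site_ids,
                   c("b", "c"))
})

test_that("alignment and class-bias filters compose as set intersection", {
  design <- cohort_design(list(sex = c(F = 0.5, M = 0.5)))
  sim <- simulate_structured_cohort(sim_config(n_sites = 60,
                                               n_samples = 100, seed = 5),
                                    design)
  keep <- colnames(sim$betas)[1:40]
  stats <- fit_sitewise_models(sim$betas, sim$meta, "sex")
  class_keep <- exclude_class_biased_sites(stats, 0.05)$retained_site_ids

  seq_result <- filter_by_alignment(sim$betas, keep)
  stats2 <- fit_sitewise_models(seq_result$betas, sim$meta, "sex")
  seq_keep <- exclude_class_biased_sites(stats2, 0.05)$retained_site_ids
  expect_setequal(seq_keep, intersect(keep, class_keep))
})
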