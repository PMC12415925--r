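# small deterministic fixtures used across test files

tiny_betas <- function(n = 10, p = 5, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(sprintf("S%04d", seq_len(n)),
                              sprintf("cg%05d", seq_len(p))))
  m
}

tiny_meta <- function(betas, ages = NULL) {
  n <- nrow(betas)
  if (is.null(ages)) ages <- seq(0, 30, length.out = n)
  data.frame(sample_id = rownames(betas), age_true = ages,
             age_reported = ages, stringsAsFactors = FALSE)
}

# two-sex cohort with three kinds of planted site behaviour, used by the
# age-association filter tests: a site with a shared age slope, one with a
# female-only slope, and a pure-noise site
sexed_cohort <- function(n = 400, seed = 11) {
  set.seed(seed)
  age <- seq(0, 30, length.out = n)
  sex <- rep(c("F", "M"), length.out = n)
  b_shared <- 0.05 * age + rnorm(n, 0, 0.1)
  b_female <- ifelse(sex == "F", 0.08 * age, 0) + rnorm(n, 0, 0.1)
  b_noise <- rnorm(n, 0, 0.1)
  betas <- cbind(cg_shared = b_shared, cg_female = b_female,
                 cg_noise = b_noise)
  rownames(betas) <- sprintf("S%04d", seq_len(n))
  meta <- data.frame(sample_id = rownames(betas), age_true = age,
                     age_reported = age, sex = sex,
                     stringsAsFactors = FALSE)
  list(betas = betas, meta = meta)
}
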