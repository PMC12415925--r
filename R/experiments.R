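#' @title Replicated clock-design experiments
#' @description Seeded scenario harnesses that quantify, on synthetic
#'   cohorts, how class bias, age bias, ageing error, train/test class
#'   overlap, feature selection and validation scheme change elastic-net
#'   clock accuracy. Every harness derives per-replicate seeds
#'   deterministically from one master seed and emits a tidy results
#'   table with one row per (grid point, replicate, arm).
#' @name experiments
NULL

# deterministic stream of sub-seeds from one master seed
.derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

.result_row <- function(summary, ...) {
  data.frame(..., mae = summary$mae, r_squared = summary$r_squared,
             pearson_r = summary$pearson_r,
             n_sites_used = summary$n_sites_used,
             stringsAsFactors = FALSE)
}

# Box-2-style two-class cohort: linear betas, classes alternating with age
# so both classes span the full age range, extra noise in the biased class
.biased_cohort <- function(config, proportion, bias_extra_sd, seed) {
  config$seed <- seed
  sim <- simulate_linear_betas(config)
  sim$meta$class <- rep(c("biased", "unbiased"),
                        length.out = config$n_samples)
  inj <- inject_class_bias(sim$betas, sim$meta, proportion, bias_extra_sd,
                           biased_class = "biased", seed = seed + 1L)
  sim$betas <- inj$betas
  sim$biased_sites <- inj$biased_sites
  sim
}

#' Class-bias sweep: mixed versus biased-only training
#'
#' For each bias proportion, simulates a two-class linear cohort in which
#' the "biased" class carries extra noise at that fraction of CpG sites,
#' then fits two clocks: one trained on 150 samples from each class
#' (mixed) and one trained only on biased-class samples, size-matched at
#' 300 so composition is not confounded with training-set size. Both are
#' evaluated on an independent test set of 150 unbiased-class samples.
#'
#' @param config A [sim_config()]; needs at least 450 samples per
#'   replicate (and 600 for the size-matched biased arm: 300 biased plus
#'   300 unbiased). Default 600.
#' @param proportions Grid of biased-site fractions in `[0, 1]`.
#' @param n_replicates Replicates per grid point (each with a fresh draw
#'   of CpG sites).
#' @param bias_extra_sd Sd of the class-specific extra noise; default
#'   equals the config's `noise_sd`.
#' @param seed Master seed.
#' @param ... Fit settings passed to [fit_clock()].
#' @return Data frame with one row per (proportion, replicate,
#'   composition in mixed/biased).
#' @export
run_class_bias_sweep <- function(config = sim_config(n_samples = 600L),
                                 proportions = c(0.05, 0.25, 0.5, 0.75, 1),
                                 n_replicates = 100L,
                                 bias_extra_sd = NULL, seed = 1L, ...) {
  if (any(proportions < 0 | proportions > 1))
    stop("`proportions` must lie in [0, 1]", call. = FALSE)
  if (config$n_samples < 450)
    stop("sample budget per replicate is ", config$n_samples,
         "; need >= 450 (150 biased + 300 unbiased)", call. = FALSE)
  if (is.null(bias_extra_sd)) bias_extra_sd <- config$bias_extra_sd
  if (is.null(bias_extra_sd)) bias_extra_sd <- config$noise_sd
  seeds <- .derive_seeds(seed, length(proportions) * n_replicates)
  out <- list(); k <- 0L
  for (pi in seq_along(proportions)) {
    for (rep_i in seq_len(n_replicates)) {
      k <- k + 1L
      s <- seeds[k]
      sim <- .biased_cohort(config, proportions[pi], bias_extra_sd, s)
      b_rows <- which(sim$meta$class == "biased")
      u_rows <- which(sim$meta$class == "unbiased")
      if (length(b_rows) < 300 || length(u_rows) < 300)
        stop("need >= 300 samples per class for the size-matched arms",
             call. = FALSE)
      set.seed(s + 2L)
      b_perm <- sample(b_rows)
      u_perm <- sample(u_rows)
      te <- u_perm[151:300]
      ages <- sim$meta$age_reported
      for (comp in c("mixed", "biased")) {
        tr <- if (comp == "mixed") c(b_perm[1:150], u_perm[1:150])
              else b_perm[1:300]
        clock <- fit_clock(sim$betas[tr, , drop = FALSE], ages[tr],
                           seed = s, ...)
        sm <- .eval_summary(predict(clock, sim$betas[te, , drop = FALSE]),
                            sim$meta$age_true[te], scheme = comp,
                            n_sites_used = clock$training_info$n_sites_nonzero)
        out[[length(out) + 1L]] <- .result_row(
          sm, scenario = "class_bias", bias_proportion = proportions[pi],
          composition = comp, replicate = rep_i, seed = s)
      }
    }
  }
  do.call(rbind, out)
}

# assemble one age-band scenario: indices for train/test
.age_scenario_split <- function(ages, scenario, n_train, n_test, seed) {
  young <- which(ages <= 15)
  old <- which(ages > 15)
  prime <- which(ages >= 5 & ages <= 20)
  set.seed(seed)
  pick <- function(pool, n) {
    if (length(pool) < n)
      stop("insufficient samples for scenario `", scenario, "`",
           call. = FALSE)
    sample(pool, n)
  }
  switch(scenario,
    unbiased = {
      tr <- pick(seq_along(ages), n_train)
      list(train = tr, test = pick(setdiff(seq_along(ages), tr), n_test))
    },
    young_biased = list(train = pick(young, n_train),
                        test = pick(old, n_test)),
    old_biased = list(train = pick(old, n_train),
                      test = pick(young, n_test)),
    prime_age = {
      tr <- pick(prime, n_train)
      list(train = tr, test = pick(setdiff(seq_along(ages), tr), n_test))
    },
    stop("unknown scenario ", scenario, call. = FALSE))
}

#' Age-bias scenarios on the non-linear simulator
#'
#' Replicates the four age-band training designs on power-law
#' methylation data: unbiased (train and test span all ages),
#' young-biased (train on ages 0-15, test on 16-30), old-biased (train
#' on 16-30, test on 0-15) and prime-age (train on 5-20, test on the
#' full 0-30 range). Old-biased training is the canonical failure mode:
#' extrapolation to young animals, whose methylation changes fastest, is
#' far worse than the reverse.
#'
#' @param config A [sim_config()]; the non-linear simulator is used and
#'   the bounded `clip01` beta scale is the default study condition.
#' @param n_replicates Replicates per scenario.
#' @param scenarios Subset of the four scenario labels.
#' @param n_train,n_test Samples per band (default 150 each).
#' @inheritParams run_class_bias_sweep
#' @return Data frame with one row per (scenario, replicate).
#' @export
run_age_scenarios <- function(config = sim_config(n_samples = 600L,
                                                  clip_mode = "clip01"),
                              n_replicates = 100L,
                              scenarios = c("unbiased", "young_biased",
                                            "old_biased", "prime_age"),
                              n_train = 150L, n_test = 150L,
                              seed = 1L, ...) {
  seeds <- .derive_seeds(seed, n_replicates)
  out <- list()
  for (rep_i in seq_len(n_replicates)) {
    s <- seeds[rep_i]
    config$seed <- s
    sim <- simulate_nonlinear_betas(config)
    ages <- sim$meta$age_true
    for (sc in scenarios) {
      sp <- .age_scenario_split(ages, sc, n_train, n_test, seed = s + 1L)
      clock <- fit_clock(sim$betas[sp$train, , drop = FALSE],
                         ages[sp$train], seed = s, ...)
      sm <- .eval_summary(predict(clock, sim$betas[sp$test, , drop = FALSE]),
                          ages[sp$test], scheme = sc,
                          n_sites_used = clock$training_info$n_sites_nonzero)
      out[[length(out) + 1L]] <- .result_row(
        sm, scenario = sc, replicate = rep_i, seed = s)
    }
  }
  do.call(rbind, out)
}

#' Ageing-error by sample-size grid
#'
#' Full factorial sweep over ageing-error standard deviations and total
#' sample sizes: each cell simulates a non-linear cohort of the given
#' size, perturbs the reported ages with `N(0, sd)` error, trains a
#' clock on the reported ages of a random half and evaluates it against
#' the *true* ages of the held-out half. Quantifies whether larger
#' samples can buy back accuracy lost to ageing error.
#'
#' @param config Base [sim_config()] (non-linear, `clip01` scale by
#'   default); `n_samples` is overridden by the grid.
#' @param sd_grid Ageing-error standard deviations in years.
#' @param n_grid Total sample sizes (training plus testing).
#' @param n_replicates Replicates per cell.
#' @param train_fraction Fraction of each cohort used for training.
#' @inheritParams run_class_bias_sweep
#' @return Data frame with one row per (sd, n, replicate).
#' @export
run_error_by_n_grid <- function(config = sim_config(clip_mode = "clip01"),
                                sd_grid = 0:5,
                                n_grid = c(50, 100, 250, 500, 1000),
                                n_replicates = 100L,
                                train_fraction = 0.5, seed = 1L, ...) {
  grid <- expand.grid(age_error_sd = sd_grid, n_total = n_grid)
  seeds <- .derive_seeds(seed, nrow(grid) * n_replicates)
  out <- list(); k <- 0L
  for (g in seq_len(nrow(grid))) {
    for (rep_i in seq_len(n_replicates)) {
      k <- k + 1L
      s <- seeds[k]
      config$seed <- s
      config$n_samples <- as.integer(grid$n_total[g])
      sim <- simulate_nonlinear_betas(config)
      sim$meta <- inject_age_error(sim$meta, grid$age_error_sd[g],
                                   seed = s + 1L)
      sm <- holdout_validate(sim$betas, sim$meta,
                             train_fraction = train_fraction,
                             seed = s + 2L, ...)
      out[[length(out) + 1L]] <- .result_row(
        sm, scenario = "error_by_n", age_error_sd = grid$age_error_sd[g],
        n_total = grid$n_total[g], replicate = rep_i, seed = s)
    }
  }
  do.call(rbind, out)
}

#' Train/test class-overlap sweep
#'
#' For a classification factor (population, sex, tissue, or an age-band
#' label), fits many clocks whose training sets contain a controlled
#' fraction of samples from the same class as the test set. At overlap 1
#' the training set is drawn entirely from the test class (within-class
#' validation); at overlap 0 it is drawn entirely from other classes.
#' When a class is exhausted, sampling falls back to with-replacement
#' draws with a warning.
#'
#' @param betas Samples-by-sites matrix (e.g. from
#'   [simulate_structured_cohort()]).
#' @param meta Metadata in matrix row order containing `factor_col`.
#' @param factor_col Name of the class factor to sweep.
#' @param test_level Class level the clocks are evaluated on.
#' @param overlap_grid Overlap proportions in `[0, 1]`.
#' @param n_clocks Clocks per overlap proportion (fresh splits each).
#' @param train_n,test_n Training and test set sizes.
#' @inheritParams run_class_bias_sweep
#' @return Data frame with one row per (overlap, clock).
#' @export
run_overlap_sweep <- function(betas, meta, factor_col, test_level,
                              overlap_grid = seq(0, 1, by = 0.25),
                              n_clocks = 100L, train_n = 75L, test_n = 30L,
                              seed = 1L, ...) {
  if (!factor_col %in% names(meta))
    stop("metadata has no column `", factor_col, "`", call. = FALSE)
  if (!test_level %in% meta[[factor_col]])
    stop("`test_level` not present in `", factor_col, "`", call. = FALSE)
  if (length(unique(meta[[factor_col]])) < 2)
    stop("factor needs >= 2 levels", call. = FALSE)
  in_class <- which(meta[[factor_col]] == test_level)
  out_class <- which(meta[[factor_col]] != test_level)
  if (length(in_class) < test_n)
    stop("class `", test_level, "` has ", length(in_class),
         " samples; need >= test_n = ", test_n, call. = FALSE)
  seeds <- .derive_seeds(seed, length(overlap_grid) * n_clocks)
  pick <- function(pool, n) {
    if (n == 0) return(integer(0))
    if (length(pool) >= n) sample(pool, n)
    else {
      warning("class pool exhausted; sampling with replacement",
              call. = FALSE)
      sample(pool, n, replace = TRUE)
    }
  }
  out <- list(); k <- 0L
  for (ov in overlap_grid) {
    n_in <- round(ov * train_n)
    for (clock_i in seq_len(n_clocks)) {
      k <- k + 1L
      s <- seeds[k]
      set.seed(s)
      te <- sample(in_class, test_n)
      tr <- c(pick(setdiff(in_class, te), n_in),
              pick(out_class, train_n - n_in))
      clock <- fit_clock(betas[tr, , drop = FALSE],
                         .train_ages(meta)[tr], seed = s, ...)
      sm <- .eval_summary(predict(clock, betas[te, , drop = FALSE]),
                          meta$age_true[te], scheme = "overlap",
                          n_sites_used = clock$training_info$n_sites_nonzero)
      out[[length(out) + 1L]] <- .result_row(
        sm, scenario = paste0("overlap_", factor_col), overlap = ov,
        replicate = clock_i, seed = s)
    }
  }
  do.call(rbind, out)
}

#' Feature-selection versus retained-bias sweep
#'
#' Re-uses the two-class biased cohort of [run_class_bias_sweep()]: at
#' each biased-site fraction it fits one clock on the full CpG panel
#' (bias retained) and one on the panel with all truly biased sites
#' removed before training (feature selection), both trained on the
#' mixed composition and tested on unbiased samples. Grid points whose
#' selection leaves fewer than 2 sites are recorded as failed rows
#' rather than raising an error.
#'
#' @inheritParams run_class_bias_sweep
#' @param removal_grid Fractions of sites made class-biased (and hence
#'   removed in the feature-selection arm).
#' @return Data frame with one row per (fraction, replicate, arm), with
#'   a `status` column (`"ok"` or `"failed"`).
#' @export
run_feature_selection_sweep <- function(config = sim_config(n_samples = 600L),
                                        removal_grid = c(0.05, 0.25, 0.5,
                                                         0.75, 0.95),
                                        n_replicates = 100L,
                                        bias_extra_sd = NULL,
                                        seed = 1L, ...) {
  if (is.null(bias_extra_sd)) bias_extra_sd <- config$noise_sd
  seeds <- .derive_seeds(seed, length(removal_grid) * n_replicates)
  out <- list(); k <- 0L
  for (frac in removal_grid) {
    for (rep_i in seq_len(n_replicates)) {
      k <- k + 1L
      s <- seeds[k]
      sim <- .biased_cohort(config, frac, bias_extra_sd, s)
      b_rows <- which(sim$meta$class == "biased")
      u_rows <- which(sim$meta$class == "unbiased")
      set.seed(s + 2L)
      u_perm <- sample(u_rows)
      tr <- c(sample(b_rows, 150), u_perm[1:150])
      te <- u_perm[151:300]
      ages <- sim$meta$age_reported
      for (arm in c("retained", "selected")) {
        cols <- if (arm == "retained") colnames(sim$betas)
                else setdiff(colnames(sim$betas), sim$biased_sites)
        if (length(cols) < 2) {
          out[[length(out) + 1L]] <- data.frame(
            scenario = "feature_selection", removal_fraction = frac,
            arm = arm, replicate = rep_i, seed = s,
            mae = NA_real_, r_squared = NA_real_, pearson_r = NA_real_,
            n_sites_used = length(cols), status = "failed",
            stringsAsFactors = FALSE)
          next
        }
        B <- sim$betas[, cols, drop = FALSE]
        clock <- fit_clock(B[tr, , drop = FALSE], ages[tr], seed = s, ...)
        sm <- .eval_summary(predict(clock, B[te, , drop = FALSE]),
                            sim$meta$age_true[te], scheme = arm,
                            n_sites_used = clock$training_info$n_sites_nonzero)
        row <- .result_row(sm, scenario = "feature_selection",
                           removal_fraction = frac, arm = arm,
                           replicate = rep_i, seed = s)
        row$status <- "ok"
        out[[length(out) + 1L]] <- row
      }
    }
  }
  do.call(rbind, out)
}

#' Feature-selection ladder on a structured cohort
#'
#' Applies the standard ladder of pre-fit filters to one cohort and
#' measures hold-out clock accuracy per rung: no feature selection,
#' genome-alignment keep-list only, age-association within both sexes,
#' age-association within all tissues, age-association within tissues
#' and sexes combined, and the full ladder (alignment plus combined
#' age-association). Records the number of sites surviving each rung;
#' rungs leaving fewer than 2 sites are reported as failed.
#'
#' @param betas,meta Cohort matrix and metadata (must contain `sex` and
#'   `tissue` columns).
#' @param keep_sites Alignment keep-list (site IDs).
#' @param n_clocks Hold-out clocks per rung.
#' @param train_n Training samples per clock.
#' @param p_threshold Per-group age-association threshold.
#' @inheritParams run_class_bias_sweep
#' @return Data frame with one row per (rung, clock) and a `status`
#'   column.
#' @export
run_selection_ladder <- function(betas, meta, keep_sites,
                                 n_clocks = 25L, train_n = NULL,
                                 p_threshold = 0.001, seed = 1L, ...) {
  if (is.null(train_n)) train_n <- round(0.6 * nrow(betas))
  sites_all <- colnames(betas)
  aligned <- intersect(sites_all, keep_sites)
  age_sex <- retain_age_associated_sites(betas, meta, "sex",
                                         p_threshold)$retained_site_ids
  age_tis <- retain_age_associated_sites(betas, meta, "tissue",
                                         p_threshold)$retained_site_ids
  rungs <- list(
    no_fs = sites_all,
    alignment = aligned,
    age_sex = age_sex,
    age_tissue = age_tis,
    age_tissue_sex = intersect(age_sex, age_tis),
    full = intersect(aligned, intersect(age_sex, age_tis))
  )
  seeds <- .derive_seeds(seed, n_clocks)
  out <- list()
  for (rung in names(rungs)) {
    cols <- rungs[[rung]]
    for (clock_i in seq_len(n_clocks)) {
      s <- seeds[clock_i]
      if (length(cols) < 2) {
        out[[length(out) + 1L]] <- data.frame(
          scenario = "selection_ladder", rung = rung, replicate = clock_i,
          seed = s, mae = NA_real_, r_squared = NA_real_,
          pearson_r = NA_real_, n_sites_used = length(cols),
          status = "failed", stringsAsFactors = FALSE)
        next
      }
      sm <- holdout_validate(betas[, cols, drop = FALSE], meta,
                             train_n = train_n, seed = s, ...)
      row <- .result_row(sm, scenario = "selection_ladder", rung = rung,
                         replicate = clock_i, seed = s)
      row$n_sites_used <- length(cols)
      row$status <- "ok"
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}

#' Paired comparison of hold-out and leave-one-out validation
#'
#' Repeats the paired design many times: draw a subset of the cohort,
#' validate once with a disjoint train/hold-out split and once with
#' leave-one-out cross-validation over the whole subset, recording both
#' accuracy estimates. Paired over repetitions, the two schemes can be
#' tested for systematic disagreement.
#'
#' Because a full internal cross-validation inside every leave-one-out
#' fold is prohibitively slow, the default chooses the penalty strength
#' once per repetition by cross-validation on the full subset and holds
#' it fixed across folds (`loo_lambda = "fixed"`); `"cv"` re-selects
#' lambda in every fold.
#'
#' @param betas,meta Cohort matrix and metadata.
#' @param n_repetitions Number of paired repetitions.
#' @param subset_n Samples drawn per repetition.
#' @param train_n Training samples for the hold-out arm (the remaining
#'   `subset_n - train_n` are the hold-out set); must be < `subset_n`.
#' @param loo_lambda `"fixed"` or `"cv"` (see Details).
#' @inheritParams run_class_bias_sweep
#' @return Data frame with one row per (repetition, scheme in
#'   holdout/loo).
#' @export
run_validation_comparison <- function(betas, meta, n_repetitions = 100L,
                                      subset_n = 400L, train_n = 250L,
                                      loo_lambda = c("fixed", "cv"),
                                      seed = 1L, ...) {
  loo_lambda <- match.arg(loo_lambda)
  if (subset_n > nrow(betas))
    stop("`subset_n` exceeds the cohort size", call. = FALSE)
  if (train_n >= subset_n)
    stop("`train_n` must be < `subset_n` (the hold-out set would be empty)",
         call. = FALSE)
  seeds <- .derive_seeds(seed, n_repetitions)
  out <- list()
  for (rep_i in seq_len(n_repetitions)) {
    s <- seeds[rep_i]
    set.seed(s)
    sub <- sample.int(nrow(betas), subset_n)
    B <- betas[sub, , drop = FALSE]
    M <- meta[sub, , drop = FALSE]
    ho <- holdout_validate(B, M, train_n = train_n, seed = s + 1L, ...)
    loo <- if (loo_lambda == "fixed") {
      ref <- fit_clock(B, .train_ages(M), seed = s + 2L, ...)
      loo_cv(B, M, lambda = ref$lambda, alpha = ref$alpha)
    } else {
      loo_cv(B, M, seed = s + 2L, ...)
    }
    out[[length(out) + 1L]] <- rbind(
      .result_row(ho, scenario = "validation_comparison",
                  scheme = "holdout", replicate = rep_i, seed = s),
      .result_row(loo, scenario = "validation_comparison",
                  scheme = "loo", replicate = rep_i, seed = s))
  }
  do.call(rbind, out)
}
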