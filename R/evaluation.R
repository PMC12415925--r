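#' Median absolute error between predicted and observed ages
#'
#' The conventional accuracy summary for epigenetic clocks: the median of
#' the absolute prediction errors (even-count medians are the midpoint of
#' the two central values).
#'
#' @param predicted,observed Numeric vectors of equal length (years).
#' @return Median absolute error in years.
#' @export
median_abs_error <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("length mismatch between predicted and observed", call. = FALSE)
  if (length(predicted) < 1) stop("empty input", call. = FALSE)
  stats::median(abs(predicted - observed))
}

.eval_summary <- function(predicted, observed, scheme, seed = NA_integer_,
                          predictions = NULL, n_sites_used = NA_integer_) {
  r <- stats::cor(predicted, observed)
  structure(list(
    mae = median_abs_error(predicted, observed),
    r_squared = r^2,
    pearson_r = r,
    n_test = length(predicted),
    n_sites_used = n_sites_used,
    predictions = predictions,
    scheme = scheme,
    seed = seed
  ), class = "evaluation_summary")
}

#' @exportS3Method base::print
print.evaluation_summary <- function(x, ...) {
  cat("<evaluation_summary>", x$scheme, "| n_test =", x$n_test,
      "| MAE =", signif(x$mae, 4), "years | R^2 =", signif(x$r_squared, 4),
      "| r =", signif(x$pearson_r, 4), "\n")
  invisible(x)
}

#' Clock accuracy metrics for one set of predictions
#'
#' Computes the median absolute error, Pearson correlation and its
#' square (the R-squared of the simple linear relationship between
#' epigenetic and chronological age) for a vector of predictions. Note
#' that a clock can combine a high R-squared with poor calibration (large
#' MAE); both numbers are always reported.
#'
#' @param predicted,observed Numeric vectors (years), at least 3 pairs;
#'   `observed` must not be constant.
#' @param scheme Label recorded in the summary.
#' @return An `evaluation_summary`: `mae`, `r_squared`, `pearson_r`,
#'   `n_test`, plus provenance fields.
#' @export
fit_metrics <- function(predicted, observed, scheme = "direct") {
  if (length(predicted) != length(observed))
    stop("length mismatch between predicted and observed", call. = FALSE)
  if (length(predicted) < 3) stop("need >= 3 pairs", call. = FALSE)
  if (stats::var(observed) == 0)
    stop("observed ages are constant; correlation undefined", call. = FALSE)
  .eval_summary(predicted, observed, scheme)
}

# ages used for training (reported when available) and truth for testing
.train_ages <- function(meta, use_reported = TRUE) {
  if (use_reported && "age_reported" %in% names(meta)) meta$age_reported
  else meta$age_true
}

#' Hold-out validation of an elastic-net clock
#'
#' Splits the cohort into disjoint seeded training and testing sets, fits
#' a clock on the training partition only (using reported ages when
#' present, the realistic field scenario) and evaluates predictions on
#' the untouched test partition against true chronological ages.
#'
#' @param betas Samples-by-sites matrix.
#' @param meta Metadata data frame in matrix row order with `age_true`
#'   (and optionally `age_reported`).
#' @param train_n Number of training samples; alternatively give
#'   `train_fraction`.
#' @param train_fraction Fraction of samples used for training, in
#'   (0, 1).
#' @param test_n Optional test-set size; default all remaining samples.
#' @param seed Integer seed for the split.
#' @param ... Fit settings passed to [fit_clock()] (`alpha`, `lambda`,
#'   `cv_folds`, ...).
#' @return An `evaluation_summary` with per-sample `predictions`.
#' @export
holdout_validate <- function(betas, meta, train_n = NULL,
                             train_fraction = NULL, test_n = NULL,
                             seed = 1L, ...) {
  n <- nrow(betas)
  if (is.null(train_n)) {
    if (is.null(train_fraction))
      stop("give `train_n` or `train_fraction`", call. = FALSE)
    if (train_fraction <= 0 || train_fraction >= 1)
      stop("`train_fraction` must be in (0, 1): both partitions must be ",
           "non-empty", call. = FALSE)
    train_n <- round(train_fraction * n)
  }
  if (train_n < 2 || train_n >= n)
    stop("`train_n` leaves an empty or degenerate partition", call. = FALSE)
  set.seed(seed)
  tr <- sample.int(n, train_n)
  te <- setdiff(seq_len(n), tr)
  if (!is.null(test_n)) {
    if (test_n > length(te))
      stop("`test_n` exceeds the remaining samples", call. = FALSE)
    te <- sample(te, test_n)
  }
  clock <- fit_clock(betas[tr, , drop = FALSE],
                     .train_ages(meta)[tr], seed = seed, ...)
  preds <- predict_ages(clock, betas[te, , drop = FALSE],
                        ages = meta$age_true[te])
  out <- .eval_summary(preds$age_epigenetic, preds$age_chronological,
                       scheme = "holdout", seed = seed, predictions = preds,
                       n_sites_used = clock$training_info$n_sites_nonzero)
  out
}

#' Leave-one-out (or leave-one-group-out) cross-validation
#'
#' Predicts each sample from a clock trained on all other samples and
#' pools the out-of-fold predictions into a single metric set. In grouped
#' mode each level of `group_by` is held out in turn, the scheme used for
#' leave-one-species-out validation of multi-species clocks. With
#' deterministic fit settings (an explicit `lambda`) the result is a pure
#' function of the data.
#'
#' @inheritParams holdout_validate
#' @param group_by Optional metadata column; hold out whole groups
#'   instead of single samples.
#' @return An `evaluation_summary` pooled over all out-of-fold
#'   predictions.
#' @export
loo_cv <- function(betas, meta, group_by = NULL, ...) {
  n <- nrow(betas)
  if (is.null(group_by)) {
    if (n < 3) stop("need >= 3 samples", call. = FALSE)
    folds <- as.list(seq_len(n))
  } else {
    if (!group_by %in% names(meta))
      stop("metadata has no column `", group_by, "`", call. = FALSE)
    levels_ <- unique(meta[[group_by]])
    if (length(levels_) < 2)
      stop("grouped LOO needs >= 2 groups", call. = FALSE)
    folds <- lapply(levels_, function(lv) which(meta[[group_by]] == lv))
  }
  train_ages <- .train_ages(meta)
  pred <- rep(NA_real_, n)
  for (fold in folds) {
    clock <- fit_clock(betas[-fold, , drop = FALSE], train_ages[-fold], ...)
    pred[fold] <- predict(clock, betas[fold, , drop = FALSE])
  }
  preds <- data.frame(sample_id = rownames(betas), age_epigenetic = pred,
                      age_chronological = meta$age_true,
                      stringsAsFactors = FALSE)
  .eval_summary(pred, meta$age_true,
                scheme = if (is.null(group_by)) "loo" else
                  paste0("loo_", group_by),
                predictions = preds)
}

#' k-fold cross-validation
#'
#' Partitions samples into `k` seeded folds of near-equal size (sizes
#' differ by at most one), trains on each complement and pools the
#' out-of-fold predictions. With `k = n` and deterministic fit settings
#' this reproduces [loo_cv()] exactly.
#'
#' @inheritParams holdout_validate
#' @param k Number of folds, between 2 and `n`.
#' @return An `evaluation_summary`.
#' @export
kfold_cv <- function(betas, meta, k, seed = 1L, ...) {
  n <- nrow(betas)
  if (k < 2 || k > n) stop("`k` must be in [2, n]", call. = FALSE)
  set.seed(seed)
  fold_id <- sample(rep(seq_len(k), length.out = n))
  train_ages <- .train_ages(meta)
  pred <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    fold <- which(fold_id == f)
    clock <- fit_clock(betas[-fold, , drop = FALSE], train_ages[-fold], ...)
    pred[fold] <- predict(clock, betas[fold, , drop = FALSE])
  }
  preds <- data.frame(sample_id = rownames(betas), age_epigenetic = pred,
                      age_chronological = meta$age_true,
                      stringsAsFactors = FALSE)
  .eval_summary(pred, meta$age_true, scheme = sprintf("%d-fold", k),
                seed = seed, predictions = preds)
}

#' Mean and percentile interval over replicate metric values
#'
#' Summarises a metric measured across bootstrap or simulation replicates
#' by its mean and a percentile confidence interval (2.5/97.5 by
#' default).
#'
#' @param values Numeric vector of replicate metric values (>= 2).
#' @param conf Confidence level (default 0.95).
#' @return Named numeric: `mean`, `lower`, `upper`.
#' @export
bootstrap_summary <- function(values, conf = 0.95) {
  if (length(values) < 2)
    stop("need >= 2 replicate values", call. = FALSE)
  a <- (1 - conf) / 2
  q <- stats::quantile(values, c(a, 1 - a), names = FALSE)
  c(mean = mean(values), lower = q[1], upper = q[2])
}
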