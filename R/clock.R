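#' Fit an elastic-net epigenetic clock
#'
#' Fits a penalized linear regression of chronological age on CpG
#' methylation with \pkg{glmnet}, the standard construction for epigenetic
#' clocks. Predictors are standardized internally and coefficients are
#' reported on the original methylation scale; the fitted model is sparse,
#' typically retaining a small subset of the input sites.
#'
#' When `lambda` is `NULL` the penalty strength is chosen by internal
#' k-fold cross-validation on mean squared error; `lambda_strategy`
#' selects either the CV-minimum (`"min"`, default) or the more
#' conservative one-standard-error rule (`"1se"`). If several lambdas tie
#' at the CV minimum, the largest (most parsimonious) is used, which is
#' the natural outcome of searching a decreasing lambda path. Supplying a
#' numeric `lambda` skips cross-validation entirely and gives a fully
#' deterministic fit.
#'
#' @param betas Samples-by-sites numeric matrix with site IDs as column
#'   names.
#' @param ages Numeric vector of training ages (years), one per row.
#' @param alpha Elastic-net mixing parameter in `[0, 1]`; 0 is ridge,
#'   1 is lasso. Default 0.5.
#' @param lambda Optional fixed penalty strength; `NULL` (default) selects
#'   it by cross-validation.
#' @param lambda_strategy `"min"` or `"1se"`; ignored when `lambda` is
#'   given.
#' @param cv_folds Number of CV folds (default 10, reduced to `n` with a
#'   warning when `n < cv_folds`).
#' @param seed Integer seed controlling CV fold assignment.
#' @param thresh Convergence threshold passed to glmnet; tightened
#'   automatically for fixed-lambda fits.
#' @return An object of class `clock_model`: `intercept` (years),
#'   `coefficients` (named vector of nonzero site weights, years per
#'   methylation unit), `alpha`, `lambda`, `standardization`, and
#'   `training_info` (n_samples, n_sites_in, n_sites_nonzero, seed,
#'   lambda_strategy).
#' @examples
#' sim <- simulate_linear_betas(sim_config(n_sites = 50, n_samples = 60))
#' clock <- fit_clock(sim$betas, sim$meta$age_true, cv_folds = 5, seed = 1)
#' clock
#' @export
fit_clock <- function(betas, ages, alpha = 0.5, lambda = NULL,
                      lambda_strategy = c("min", "1se"),
                      cv_folds = 10L, seed = 1L, thresh = NULL) {
  lambda_strategy <- match.arg(lambda_strategy)
  betas <- as.matrix(betas)
  if (is.null(colnames(betas)))
    stop("`betas` must have site IDs as column names", call. = FALSE)
  if (length(ages) != nrow(betas))
    stop("length(ages) must equal nrow(betas)", call. = FALSE)
  if (!all(is.finite(ages))) stop("ages must be finite", call. = FALSE)
  if (stats::var(ages) == 0)
    stop("constant age vector: nothing to fit", call. = FALSE)
  if (ncol(betas) < 1) stop("matrix has no sites", call. = FALSE)
  site_sd <- apply(betas, 2, stats::sd)
  if (all(site_sd == 0))
    stop("all sites are constant: nothing to fit", call. = FALSE)
  if (alpha < 0 || alpha > 1) stop("`alpha` must be in [0, 1]", call. = FALSE)

  n <- nrow(betas)
  used_cv <- is.null(lambda)
  if (used_cv) {
    if (cv_folds < 2) stop("`cv_folds` must be >= 2", call. = FALSE)
    if (n < cv_folds) {
      warning("reducing cv_folds from ", cv_folds, " to n = ", n)
      cv_folds <- n
    }
    set.seed(seed)
    foldid <- sample(rep(seq_len(cv_folds), length.out = n))
    cv <- glmnet::cv.glmnet(betas, ages, alpha = alpha, foldid = foldid,
                            standardize = TRUE)
    lambda <- if (lambda_strategy == "min") cv$lambda.min else cv$lambda.1se
    fit <- cv$glmnet.fit
  } else {
    if (lambda < 0) stop("`lambda` must be >= 0", call. = FALSE)
    if (is.null(thresh)) thresh <- 1e-7
    # fit a short decreasing path ending at the target lambda: glmnet's
    # warm starts make this faster and better-converged than a cold
    # single-lambda fit
    lam_path <- if (lambda > 0) lambda * 10^seq(3, 0, length.out = 12)
                else c(10^seq(-1, -8, length.out = 10), 0)
    fit <- glmnet::glmnet(betas, ages, alpha = alpha, lambda = lam_path,
                          standardize = TRUE, thresh = thresh)
  }
  cf <- as.numeric(stats::coef(fit, s = lambda, exact = FALSE))
  names(cf) <- c("(Intercept)", colnames(betas))
  nz <- cf[-1][cf[-1] != 0]
  structure(list(
    intercept = unname(cf[1]),
    coefficients = nz,
    alpha = alpha,
    lambda = lambda,
    standardization = list(
      center = colMeans(betas)[names(nz)],
      scale = site_sd[names(nz)],
      note = "coefficients are on the original methylation scale"
    ),
    training_info = list(
      n_samples = n, n_sites_in = ncol(betas),
      n_sites_nonzero = length(nz), seed = as.integer(seed),
      lambda_strategy = if (used_cv) lambda_strategy else "fixed"
    )
  ), class = "clock_model")
}

#' @exportS3Method base::print
print.clock_model <- function(x, ...) {
  ti <- x$training_info
  cat("<clock_model> elastic net (alpha =", x$alpha,
      ", lambda =", signif(x$lambda, 4), ")\n")
  cat("  trained on", ti$n_samples, "samples x", ti$n_sites_in, "sites;",
      ti$n_sites_nonzero, "sites carry nonzero weight\n")
  invisible(x)
}

#' @export
predict.clock_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  need <- names(object$coefficients)
  missing_sites <- setdiff(need, colnames(newdata))
  if (length(missing_sites) > 0)
    stop("matrix is missing required clock sites: ",
         paste(utils::head(missing_sites, 10), collapse = ", "),
         if (length(missing_sites) > 10) " ...", call. = FALSE)
  pred <- if (length(need) == 0) {
    rep(object$intercept, nrow(newdata))
  } else {
    as.numeric(newdata[, need, drop = FALSE] %*% object$coefficients) +
      object$intercept
  }
  names(pred) <- rownames(newdata)
  pred
}

#' Predict epigenetic ages and acceleration for a cohort
#'
#' Scores a fitted clock on a methylation matrix, matching sites by ID
#' (column order is irrelevant), and, when chronological ages are
#' supplied, computes both forms of epigenetic age acceleration: the raw
#' difference (epigenetic minus chronological age) and the residual from
#' regressing epigenetic on chronological age within the scored set.
#'
#' @param model A `clock_model` from [fit_clock()].
#' @param betas Methylation matrix containing every nonzero-coefficient
#'   site of the model.
#' @param ages Optional chronological ages (years) in matrix row order.
#' @return A data frame with `sample_id`, `age_epigenetic` and, when ages
#'   are given, `age_chronological`, `acceleration_delta` and
#'   `acceleration_residual`.
#' @export
predict_ages <- function(model, betas, ages = NULL) {
  stopifnot(inherits(model, "clock_model"))
  pred <- predict(model, betas)
  ids <- rownames(betas)
  if (is.null(ids)) ids <- sprintf("S%04d", seq_len(nrow(betas)))
  out <- data.frame(sample_id = ids, age_epigenetic = unname(pred),
                    stringsAsFactors = FALSE)
  if (!is.null(ages)) {
    if (length(ages) != nrow(betas))
      stop("length(ages) must equal nrow(betas)", call. = FALSE)
    out$age_chronological <- ages
    out$acceleration_delta <- out$age_epigenetic - ages
    out$acceleration_residual <-
      if (nrow(out) >= 3 && stats::var(ages) > 0)
        age_acceleration(out$age_epigenetic, ages, method = "residual")
      else NA_real_
  }
  out
}

#' Epigenetic age acceleration
#'
#' Computes per-sample age acceleration either as the raw difference
#' between epigenetic and chronological age (`"delta"`) or as the
#' residual of the least-squares regression of epigenetic on
#' chronological age (`"residual"`). The residual form removes any
#' systematic calibration offset or slope, isolating relative
#' acceleration within the evaluated set; its mean is zero by
#' construction.
#'
#' @param predicted Epigenetic ages (years).
#' @param chronological Chronological ages (years).
#' @param method `"delta"` or `"residual"`.
#' @return Numeric vector of accelerations in years.
#' @export
age_acceleration <- function(predicted, chronological,
                             method = c("delta", "residual")) {
  method <- match.arg(method)
  if (length(predicted) != length(chronological))
    stop("length mismatch", call. = FALSE)
  if (method == "delta") return(predicted - chronological)
  if (length(predicted) < 3)
    stop("residual method needs >= 3 samples", call. = FALSE)
  if (stats::var(chronological) == 0)
    stop("residual method undefined for constant chronological ages",
         call. = FALSE)
  unname(stats::resid(stats::lm(predicted ~ chronological)))
}
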