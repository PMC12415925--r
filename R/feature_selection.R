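#' @title CpG feature selection
#' @description Pre-fit reduction of the CpG feature space: genome
#'   alignment keep-lists, per-site linear-model class filters, per-group
#'   age-association filters, and variance filtering. All filters return a
#'   `selection_report` accounting for every input site exactly once.
#' @name feature_selection
NULL

.selection_report <- function(input_sites, retained, reasons, thresholds) {
  excluded <- setdiff(input_sites, retained)
  stopifnot(length(intersect(retained, excluded)) == 0)
  structure(list(
    n_input_sites = length(input_sites),
    retained_site_ids = retained,
    excluded = data.frame(site_id = excluded,
                          reason = unname(reasons[excluded]),
                          stringsAsFactors = FALSE),
    thresholds = thresholds
  ), class = "selection_report")
}

#' @exportS3Method base::print
print.selection_report <- function(x, ...) {
  cat("<selection_report>", length(x$retained_site_ids), "of",
      x$n_input_sites, "sites retained\n")
  if (nrow(x$excluded) > 0)
    print(table(x$excluded$reason))
  invisible(x)
}

#' Restrict a methylation matrix to genome-aligned sites
#'
#' Keeps only the CpG sites present in an alignment keep-list, the
#' standard first reduction when a multi-species methylation panel is
#' applied to one species: sites whose probe sequence does not align to
#' that species' genome are removed before any clock fitting.
#'
#' @param betas Samples-by-sites matrix with site IDs as column names.
#' @param keep_sites Character vector of site IDs to retain.
#' @return A list with the restricted `betas` and a `report`
#'   (`selection_report`).
#' @export
filter_by_alignment <- function(betas, keep_sites) {
  if (length(keep_sites) == 0)
    stop("`keep_sites` is empty", call. = FALSE)
  sites <- colnames(betas)
  retained <- sites[sites %in% keep_sites]
  if (length(retained) == 0)
    stop("no sites in the matrix align with the keep-list; nothing to train on",
         call. = FALSE)
  reasons <- stats::setNames(rep("alignment", length(sites)), sites)
  report <- .selection_report(sites, retained, reasons,
                              list(keep_list_size = length(keep_sites)))
  list(betas = betas[, retained, drop = FALSE], report = report)
}

# shared vectorised multi-response OLS: Y (n x m) on design X (n x k).
# returns coefs, rss, df_resid
.ols_multi <- function(X, Y) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient design matrix", call. = FALSE)
  coefs <- qr.coef(qrX, Y)
  res <- qr.resid(qrX, Y)
  list(coefs = coefs, rss = colSums(res^2),
       df_resid = nrow(X) - ncol(X), qr = qrX)
}

#' Per-site linear models of methylation on age and class factors
#'
#' Fits, at every CpG site, an ordinary least-squares model of
#' methylation on chronological age plus the requested classification
#' factors (tissue, sex, population, ...). Reports per site: the age
#' slope and its t-test p-value, and for each factor the joint F-test
#' p-value for that factor's coefficients (full model versus the model
#' with the factor removed). Factors with a single represented level are
#' dropped with a warning. The computation is vectorised across sites
#' (one QR decomposition per model, shared by all sites).
#'
#' @param betas Samples-by-sites matrix.
#' @param meta Metadata data frame in matrix row order.
#' @param factors Character vector of metadata column names to test.
#' @param age_col Metadata column holding ages (default `age_true`).
#' @return A data frame of class `sitewise_stats` with columns `site_id`,
#'   `age_slope`, `age_p`, one `<factor>_p` column per retained factor,
#'   and `n_used`; the retained factors are recorded in the `factors`
#'   attribute.
#' @export
fit_sitewise_models <- function(betas, meta, factors,
                                age_col = "age_true") {
  if (!age_col %in% names(meta))
    stop("metadata has no column `", age_col, "`", call. = FALSE)
  missing_f <- setdiff(factors, names(meta))
  if (length(missing_f) > 0)
    stop("unknown factors: ", paste(missing_f, collapse = ", "), call. = FALSE)
  keep <- vapply(factors, function(f) {
    ok <- length(unique(meta[[f]])) >= 2
    if (!ok) warning("factor `", f, "` has a single level; dropped")
    ok
  }, logical(1))
  factors <- factors[keep]
  age <- meta[[age_col]]
  n <- nrow(betas)
  df_terms <- stats::as.formula(
    paste("~", paste(c(age_col, factors), collapse = " + ")))
  X <- stats::model.matrix(df_terms, data = meta)
  if (n <= ncol(X))
    stop("too few samples (", n, ") for ", ncol(X), " model terms",
         call. = FALSE)
  full <- .ols_multi(X, betas)
  sigma2 <- full$rss / full$df_resid
  XtXinv <- chol2inv(chol(crossprod(X)))
  age_ix <- which(colnames(X) == age_col)
  se_age <- sqrt(XtXinv[age_ix, age_ix] * sigma2)
  tval <- full$coefs[age_ix, ] / se_age
  out <- data.frame(
    site_id = colnames(betas),
    age_slope = unname(full$coefs[age_ix, ]),
    age_p = unname(2 * stats::pt(-abs(tval), full$df_resid)),
    stringsAsFactors = FALSE
  )
  assign_map <- attr(X, "assign")
  term_labels <- attr(stats::terms(df_terms), "term.labels")
  for (f in factors) {
    cols <- which(assign_map == match(f, term_labels))
    Xr <- X[, -cols, drop = FALSE]
    red <- .ols_multi(Xr, betas)
    df1 <- length(cols)
    Fval <- ((red$rss - full$rss) / df1) / (full$rss / full$df_resid)
    out[[paste0(f, "_p")]] <-
      stats::pf(Fval, df1, full$df_resid, lower.tail = FALSE)
  }
  out$n_used <- n
  attr(out, "factors") <- factors
  class(out) <- c("sitewise_stats", "data.frame")
  out
}

#' Exclude CpG sites with class-biased methylation
#'
#' Removes every site whose methylation differs significantly by any
#' tested class factor, using the raw per-factor F-test p-values from
#' [fit_sitewise_models()] with no multiple-testing adjustment — the
#' conventional raw `p < 0.001` screen for class-confounded clock sites.
#'
#' @param stats A `sitewise_stats` data frame.
#' @param p_threshold Exclusion threshold on the raw p-value
#'   (default 0.001); a site is excluded iff any factor p-value is
#'   strictly below it.
#' @return A `selection_report`.
#' @export
exclude_class_biased_sites <- function(stats, p_threshold = 0.001) {
  stopifnot(inherits(stats, "sitewise_stats"))
  factors <- attr(stats, "factors")
  pcols <- paste0(factors, "_p")
  if (length(pcols) == 0)
    stop("no class factors in `stats`", call. = FALSE)
  pmat <- as.matrix(stats[, pcols, drop = FALSE])
  biased <- apply(pmat < p_threshold, 1, any)
  retained <- stats$site_id[!biased]
  reasons <- stats::setNames(rep("class_bias", nrow(stats)), stats$site_id)
  .selection_report(stats$site_id, retained, reasons,
                    list(p_threshold = p_threshold, factors = factors))
}

# vectorised per-site simple regression of methylation on age:
# returns two-sided p-value of the slope per site
.agewise_p <- function(betas, age) {
  n <- length(age)
  if (n < 3) stop("need >= 3 samples per group", call. = FALSE)
  r <- suppressWarnings(stats::cor(age, betas))
  r[is.na(r)] <- 0  # constant site: no association
  tval <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  as.numeric(2 * stats::pt(-abs(tval), n - 2))
}

#' Retain sites age-associated within every group
#'
#' Keeps a CpG site only if its methylation-age regression slope is
#' significant (raw p below the threshold) within *every* level of the
#' grouping factor — e.g. in both sexes, or in every tissue. Sites whose
#' apparent age signal is carried by one class only are removed along
#' with sites lacking any age signal.
#'
#' @param betas Samples-by-sites matrix.
#' @param meta Metadata data frame in matrix row order.
#' @param group_col Name of the grouping factor column.
#' @param p_threshold Per-group significance threshold (default 0.001).
#' @param age_col Metadata age column (default `age_true`).
#' @return A `selection_report` (reason `no_age_signal`).
#' @export
retain_age_associated_sites <- function(betas, meta, group_col,
                                        p_threshold = 0.001,
                                        age_col = "age_true") {
  if (!group_col %in% names(meta))
    stop("metadata has no column `", group_col, "`", call. = FALSE)
  levels_ <- unique(meta[[group_col]])
  counts <- table(meta[[group_col]])
  if (any(counts < 3))
    stop("each group needs >= 3 samples; got ",
         paste(names(counts)[counts < 3], collapse = ", "), call. = FALSE)
  keep <- rep(TRUE, ncol(betas))
  for (lv in levels_) {
    rows <- meta[[group_col]] == lv
    p <- .agewise_p(betas[rows, , drop = FALSE], meta[[age_col]][rows])
    keep <- keep & (p < p_threshold)
  }
  retained <- colnames(betas)[keep]
  reasons <- stats::setNames(rep("no_age_signal", ncol(betas)),
                             colnames(betas))
  .selection_report(colnames(betas), retained, reasons,
                    list(p_threshold = p_threshold, group = group_col))
}

#' Retain the most variable CpG sites
#'
#' Unsupervised variance filter: keeps either the `top_k` sites with the
#' highest across-sample variance (ties broken deterministically by site
#' ID order) or all sites with variance at least `min_variance`. Low
#' variance sites are unlikely to discriminate among ages and mostly add
#' noise to the feature space.
#'
#' @param betas Samples-by-sites matrix.
#' @param top_k Number of sites to keep (exactly one of `top_k` /
#'   `min_variance` must be given).
#' @param min_variance Variance cutoff.
#' @return A `selection_report` (reason `low_variance`).
#' @export
variance_filter <- function(betas, top_k = NULL, min_variance = NULL) {
  if (is.null(top_k) == is.null(min_variance))
    stop("give exactly one of `top_k` or `min_variance`", call. = FALSE)
  v <- apply(betas, 2, stats::var)
  sites <- colnames(betas)
  if (!is.null(top_k)) {
    if (top_k > length(sites))
      stop("`top_k` exceeds the number of sites", call. = FALSE)
    ord <- order(-v, sites)
    retained <- sites[sort(ord[seq_len(top_k)])]
    thresholds <- list(top_k = top_k)
  } else {
    retained <- sites[v >= min_variance]
    thresholds <- list(min_variance = min_variance)
  }
  reasons <- stats::setNames(rep("low_variance", length(sites)), sites)
  .selection_report(sites, retained, reasons, thresholds)
}
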