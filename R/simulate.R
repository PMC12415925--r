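#' Simulation configuration for synthetic methylation cohorts
#'
#' Bundles every generative parameter of the linear and non-linear
#' age-methylation simulators into a single validated object. The defaults
#' describe the canonical simulated cohort used throughout the package's
#' experiments: 500 age-associated CpG sites measured in individuals whose
#' ages are spread evenly across a 0-30 year lifespan.
#'
#' Two generative models are supported. The *linear* model draws a per-site
#' slope `x` from `Uniform(slope_min, slope_max)` and sets
#' `beta = x * age + eps` with `eps ~ N(0, noise_sd)`. The *non-linear*
#' model draws a per-site exponent `x` from
#' `N(exponent_mean, exponent_sd)` and sets `beta = age^x + eps`.
#'
#' `clip_mode` controls the measurement scale. `"raw"` reproduces the model
#' formulas unmodified, so values may fall outside `[0, 1]`. `"clip01"`
#' affinely rescales each site's noise-free trajectory to `[0.05, 0.95]`
#' before adding noise and finally clips to `[0, 1]`, giving values on the
#' bounded beta-value (methylation proportion) scale.
#'
#' @param n_sites Number of CpG sites to simulate (positive integer).
#' @param n_samples Number of individuals (positive integer).
#' @param age_min,age_max Age range in years; ages are assigned evenly
#'   across the range.
#' @param slope_range Length-2 numeric, bounds of the uniform slope
#'   distribution for the linear model.
#' @param noise_sd Standard deviation of the additive noise `eps`. Default
#'   0.5; the non-linear simulator overrides an unset value with 0.8.
#' @param exponent_mean,exponent_sd Mean and sd of the normal exponent
#'   distribution for the non-linear model.
#' @param bias_proportion Fraction of sites receiving class-specific extra
#'   noise, in `[0, 1]` (used by [inject_class_bias()] defaults).
#' @param bias_extra_sd Standard deviation of the additional class-bias
#'   noise. `NULL` means "same as `noise_sd`".
#' @param age_error_sd Standard deviation, in years, of ageing error added
#'   to reported ages (used by [inject_age_error()] defaults).
#' @param clip_mode `"raw"` or `"clip01"` (see Details).
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_linear_betas()], [simulate_nonlinear_betas()]
#' @export
sim_config <- function(n_sites = 500L, n_samples = 300L,
                       age_min = 0, age_max = 30,
                       slope_range = c(-0.1, 0.1),
                       noise_sd = 0.5,
                       exponent_mean = 2, exponent_sd = 0.35,
                       bias_proportion = 0, bias_extra_sd = NULL,
                       age_error_sd = 0,
                       clip_mode = c("raw", "clip01"),
                       seed = 1L) {
  clip_mode <- match.arg(clip_mode)
  if (length(n_sites) != 1L || !is.finite(n_sites) || n_sites < 1)
    stop("`n_sites` must be a positive integer", call. = FALSE)
  if (length(n_samples) != 1L || !is.finite(n_samples) || n_samples < 1)
    stop("`n_samples` must be a positive integer", call. = FALSE)
  if (!is.numeric(age_min) || !is.numeric(age_max) || age_min >= age_max)
    stop("`age_min` must be strictly less than `age_max`", call. = FALSE)
  if (length(slope_range) != 2L || slope_range[1] > slope_range[2])
    stop("`slope_range` must be increasing bounds", call. = FALSE)
  for (nm in c("noise_sd", "exponent_sd", "age_error_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0)
      stop("`", nm, "` must be a single non-negative number", call. = FALSE)
  }
  if (!is.null(bias_extra_sd) && (!is.numeric(bias_extra_sd) || bias_extra_sd < 0))
    stop("`bias_extra_sd` must be non-negative", call. = FALSE)
  if (bias_proportion < 0 || bias_proportion > 1)
    stop("`bias_proportion` must be in [0, 1]", call. = FALSE)
  structure(list(
    n_sites = as.integer(n_sites), n_samples = as.integer(n_samples),
    age_min = age_min, age_max = age_max,
    slope_range = as.numeric(slope_range),
    noise_sd = noise_sd,
    exponent_mean = exponent_mean, exponent_sd = exponent_sd,
    bias_proportion = bias_proportion, bias_extra_sd = bias_extra_sd,
    age_error_sd = age_error_sd, clip_mode = clip_mode,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @exportS3Method base::print
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_samples, "samples x", x$n_sites, "sites; ages",
      x$age_min, "-", x$age_max, "; noise_sd", x$noise_sd,
      "; clip_mode", x$clip_mode, "; seed", x$seed, "\n")
  invisible(x)
}

# evenly spaced ages across the configured range, with sample / site IDs
.sim_frame <- function(config) {
  ages <- seq(config$age_min, config$age_max, length.out = config$n_samples)
  list(
    ages = ages,
    sample_ids = sprintf("S%04d", seq_len(config$n_samples)),
    site_ids = sprintf("cg%05d", seq_len(config$n_sites))
  )
}

# rescale each column's noise-free trajectory to [0.05, 0.95], add noise on
# that scale, clip to [0, 1]
.apply_scale <- function(signal, noise, clip_mode) {
  if (clip_mode == "raw") return(signal + noise)
  rng <- apply(signal, 2, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1  # flat site: map to the centre of the band
  scaled <- sweep(sweep(signal, 2, rng[1, ], "-"), 2, span, "/") * 0.9 + 0.05
  pmin(pmax(scaled + noise, 0), 1)
}

.finish_sim <- function(values, frame, site_params, config) {
  dimnames(values) <- list(frame$sample_ids, frame$site_ids)
  meta <- data.frame(
    sample_id = frame$sample_ids,
    age_true = frame$ages,
    age_reported = frame$ages,
    stringsAsFactors = FALSE
  )
  structure(list(betas = values, meta = meta,
                 site_params = site_params, config = config),
            class = "beta_sim")
}

#' @exportS3Method base::print
print.beta_sim <- function(x, ...) {
  cat("<beta_sim>", nrow(x$betas), "samples x", ncol(x$betas), "CpG sites (",
      x$site_params$model[1], "model, clip_mode", x$config$clip_mode, ")\n")
  invisible(x)
}

#' Simulate linearly age-associated methylation values
#'
#' Generates a samples-by-sites matrix in which each site follows
#' `beta = x * age + eps`, with the per-site slope `x` drawn once from a
#' uniform distribution and `eps ~ N(0, noise_sd)` drawn per observation.
#' Ages are assigned evenly across `[age_min, age_max]`.
#'
#' @param config A [sim_config()] object.
#' @return A `beta_sim` list: `betas` (numeric matrix, samples in rows),
#'   `meta` (data frame with `sample_id`, `age_true`, `age_reported`),
#'   `site_params` (data frame with the drawn slope per site, for
#'   truth-known testing) and the `config` used.
#' @examples
#' sim <- simulate_linear_betas(sim_config(n_sites = 20, n_samples = 30))
#' dim(sim$betas)
#' @export
simulate_linear_betas <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  frame <- .sim_frame(config)
  set.seed(config$seed)
  x <- stats::runif(config$n_sites, config$slope_range[1], config$slope_range[2])
  signal <- outer(frame$ages, x)
  noise <- matrix(stats::rnorm(length(signal), 0, config$noise_sd),
                  nrow = nrow(signal))
  values <- .apply_scale(signal, noise, config$clip_mode)
  site_params <- data.frame(site_id = frame$site_ids, slope = x,
                            model = "linear", stringsAsFactors = FALSE)
  .finish_sim(values, frame, site_params, config)
}

#' Simulate non-linearly age-associated methylation values
#'
#' Generates methylation values following the power-law model
#' `beta = age^x + eps`, where the per-site exponent `x` is drawn from
#' `N(exponent_mean, exponent_sd)` and `eps ~ N(0, noise_sd)`. Because a
#' power of a negative base is undefined, `age_min` must be non-negative.
#' If the config's `noise_sd` equals the linear default (0.5) it is raised
#' to 0.8, the conventional noise level for this model.
#'
#' On the raw scale the power-law values grow without bound with age; in
#' `clip_mode = "clip01"` each site's noise-free curve is rescaled to the
#' bounded beta-value scale before the noise is added, which is the scale
#' used by the age-bias experiments.
#'
#' @inheritParams simulate_linear_betas
#' @return A `beta_sim` list; `site_params` carries the drawn exponents.
#' @export
simulate_nonlinear_betas <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$age_min < 0)
    stop("non-linear model requires non-negative ages (age_min >= 0)",
         call. = FALSE)
  if (identical(config$noise_sd, 0.5)) config$noise_sd <- 0.8
  frame <- .sim_frame(config)
  set.seed(config$seed)
  x <- stats::rnorm(config$n_sites, config$exponent_mean, config$exponent_sd)
  signal <- outer(frame$ages, x, function(y, xx) y^xx)
  noise <- matrix(stats::rnorm(length(signal), 0, config$noise_sd),
                  nrow = nrow(signal))
  values <- .apply_scale(signal, noise, config$clip_mode)
  site_params <- data.frame(site_id = frame$site_ids, exponent = x,
                            model = "nonlinear", stringsAsFactors = FALSE)
  .finish_sim(values, frame, site_params, config)
}

# round half away from zero (base round() rounds half to even)
.round_half_up <- function(x) floor(x + 0.5)

#' Inject class-specific extra noise into a subset of CpG sites
#'
#' Weakens the age-methylation association for one class of samples by
#' adding zero-mean Gaussian noise, at a seeded random subset of sites, to
#' the rows belonging to that class. This emulates a cohort in which some
#' category of sample (a tissue, a sex, a population) carries noisier
#' age-related methylation than the rest.
#'
#' Exactly `round(bias_proportion * n_sites)` sites are selected without
#' replacement (half-counts round away from zero).
#'
#' @param betas Samples-by-sites numeric matrix with dimnames.
#' @param meta Metadata data frame with one row per sample, in matrix row
#'   order, containing `class_col`.
#' @param bias_proportion Fraction of sites to perturb, in `[0, 1]`.
#' @param bias_extra_sd Standard deviation of the added noise.
#' @param biased_class Label (level of `class_col`) whose samples receive
#'   the extra noise.
#' @param class_col Name of the metadata column holding class labels.
#' @param seed Integer seed for site selection and noise draws.
#' @return A list with `betas` (perturbed matrix) and `biased_sites`
#'   (character vector of perturbed site IDs).
#' @export
inject_class_bias <- function(betas, meta, bias_proportion, bias_extra_sd,
                              biased_class, class_col = "class", seed = 1L) {
  if (bias_proportion < 0 || bias_proportion > 1)
    stop("`bias_proportion` must be in [0, 1]", call. = FALSE)
  if (bias_extra_sd < 0) stop("`bias_extra_sd` must be >= 0", call. = FALSE)
  if (!class_col %in% names(meta))
    stop("metadata has no column `", class_col, "`", call. = FALSE)
  if (!biased_class %in% meta[[class_col]])
    stop("class label `", biased_class, "` not present in metadata",
         call. = FALSE)
  n_sites <- ncol(betas)
  n_pick <- .round_half_up(bias_proportion * n_sites)
  set.seed(seed)
  picked <- sort(sample.int(n_sites, n_pick))
  site_ids <- colnames(betas)[picked]
  if (n_pick > 0 && bias_extra_sd > 0) {
    rows <- which(meta[[class_col]] == biased_class)
    extra <- matrix(stats::rnorm(length(rows) * n_pick, 0, bias_extra_sd),
                    nrow = length(rows))
    betas[rows, picked] <- betas[rows, picked] + extra
  }
  list(betas = betas, biased_sites = site_ids)
}

#' Add ageing error to reported ages
#'
#' Perturbs `age_reported` with `N(0, age_error_sd)` draws while leaving
#' `age_true` untouched, emulating cohorts where chronological ages are
#' estimated rather than known. Clocks trained on `age_reported` but
#' evaluated against `age_true` quantify the cost of that error.
#'
#' @param meta Metadata data frame with `age_true`.
#' @param age_error_sd Standard deviation of the error, in years.
#' @param seed Integer seed.
#' @param truncate_at_zero If `TRUE`, negative perturbed ages are set to 0;
#'   the default keeps the raw draws.
#' @return The metadata with `age_reported` replaced.
#' @export
inject_age_error <- function(meta, age_error_sd, seed = 1L,
                             truncate_at_zero = FALSE) {
  if (age_error_sd < 0) stop("`age_error_sd` must be >= 0", call. = FALSE)
  set.seed(seed)
  rep_age <- meta$age_true + stats::rnorm(nrow(meta), 0, age_error_sd)
  if (truncate_at_zero) rep_age <- pmax(rep_age, 0)
  meta$age_reported <- rep_age
  meta
}

#' Describe the class structure of a simulated cohort
#'
#' A cohort design specifies, for each classification factor (sex, tissue,
#' population, ...), the proportion of samples in each level, plus an
#' optional list of planted class effects: sites whose methylation is
#' shifted and/or whose age slope is multiplied for samples in a given
#' level. Planted effects make the generated data a truth-known benchmark
#' for class-bias detection and feature selection.
#'
#' @param factors Named list; each element is a named numeric vector of
#'   level proportions summing to 1, e.g.
#'   `list(tissue = c(blood = 0.43, skin = 0.57))`.
#' @param effects List of planted effects, each a list with elements
#'   `factor` (factor name), `level` (affected class), `sites` (integer
#'   site indices), and one or both of `shift` (additive methylation
#'   offset) and `slope_mult` (multiplier on the site's age slope for that
#'   class).
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(factors, effects = list()) {
  if (!is.list(factors) || is.null(names(factors)) || any(names(factors) == ""))
    stop("`factors` must be a named list of proportion vectors", call. = FALSE)
  for (nm in names(factors)) {
    p <- factors[[nm]]
    if (is.null(names(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("proportions for factor `", nm, "` must be named, non-negative ",
           "and sum to 1", call. = FALSE)
  }
  for (ef in effects) {
    if (!all(c("factor", "level", "sites") %in% names(ef)))
      stop("each effect needs `factor`, `level` and `sites`", call. = FALSE)
    if (!ef$factor %in% names(factors))
      stop("effect refers to unknown factor `", ef$factor, "`", call. = FALSE)
    if (!ef$level %in% names(factors[[ef$factor]]))
      stop("effect refers to unknown level `", ef$level, "`", call. = FALSE)
  }
  structure(list(factors = factors, effects = effects),
            class = "cohort_design")
}

# deterministic largest-remainder allocation of n samples to proportions
.allocate_counts <- function(n, props) {
  raw <- props * n
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  counts
}

#' Simulate a structured multi-class methylation cohort
#'
#' Generates a linear age-methylation cohort (see
#' [simulate_linear_betas()]) and overlays the class structure of a
#' [cohort_design()]: each sample is assigned a level of every factor so
#' that level frequencies match the design proportions within rounding,
#' and each planted effect perturbs its designated sites for samples in
#' the affected class. Assignments are shuffled (seeded) so classes are
#' not confounded with age.
#'
#' @param config A [sim_config()].
#' @param design A [cohort_design()].
#' @return A `beta_sim` list whose `meta` carries one column per factor
#'   and whose `effect_sites` element lists the planted effect site IDs
#'   per effect, for truth-known testing.
#' @export
simulate_structured_cohort <- function(config, design) {
  stopifnot(inherits(config, "sim_config"), inherits(design, "cohort_design"))
  sim <- simulate_linear_betas(config)
  n <- config$n_samples
  set.seed(config$seed + 1L)
  for (nm in names(design$factors)) {
    counts <- .allocate_counts(n, design$factors[[nm]])
    labels <- rep(names(counts), counts)
    sim$meta[[nm]] <- sample(labels)
  }
  effect_sites <- list()
  for (k in seq_along(design$effects)) {
    ef <- design$effects[[k]]
    if (any(ef$sites < 1 | ef$sites > config$n_sites))
      stop("effect site indices outside 1..n_sites", call. = FALSE)
    rows <- which(sim$meta[[ef$factor]] == ef$level)
    if (!is.null(ef$shift))
      sim$betas[rows, ef$sites] <- sim$betas[rows, ef$sites] + ef$shift
    if (!is.null(ef$slope_mult)) {
      slopes <- sim$site_params$slope[ef$sites]
      ages <- sim$meta$age_true[rows]
      sim$betas[rows, ef$sites] <- sim$betas[rows, ef$sites] +
        outer(ages, slopes * (ef$slope_mult - 1))
    }
    effect_sites[[k]] <- list(factor = ef$factor, level = ef$level,
                              sites = colnames(sim$betas)[ef$sites])
  }
  sim$design <- design
  sim$effect_sites <- effect_sites
  sim
}
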