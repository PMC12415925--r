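#' @title On-disk formats
#' @description Delimited-text readers and writers for methylation
#'   matrices, sample metadata, site keep-lists and simulation configs,
#'   plus JSON serialization of fitted clocks. Every writer/reader pair
#'   is a lossless round trip for its type.
#' @name io
NULL

CLOCK_SCHEMA_VERSION <- "1.0"

# 17 significant digits: enough for doubles to round-trip bit-exactly
.fmt_num <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  gsub(" ", "", out)
}

.fmt_df <- function(df) {
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- .fmt_num(df[[j]])
  df
}

#' Read a methylation beta-value matrix from delimited text
#'
#' Expects samples in rows: a header row of site IDs and a first column
#' of sample IDs. Use `transpose = TRUE` for array-style files with
#' sites in rows.
#'
#' @param path File path.
#' @param delim Field delimiter (`","` default; `"\t"` for TSV).
#' @param transpose If `TRUE`, the file holds sites in rows and is
#'   transposed after reading.
#' @return Numeric matrix, samples in rows, with dimnames.
#' @export
read_beta_matrix <- function(path, delim = ",", transpose = FALSE) {
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicated sample ID(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(names(df)[-1]))
    stop("duplicated site ID(s): ",
         paste(unique(names(df)[-1][duplicated(names(df)[-1])]),
               collapse = ", "), call. = FALSE)
  vals <- df[, -1, drop = FALSE]
  bad <- which(!vapply(vals, is.numeric, logical(1)))
  if (length(bad) > 0)
    stop("non-numeric values in column(s): ",
         paste(names(vals)[bad], collapse = ", "), call. = FALSE)
  m <- as.matrix(vals)
  if (!all(is.finite(m))) {
    ij <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    stop("non-finite value at row ", ij[1], ", column ", ij[2],
         call. = FALSE)
  }
  rownames(m) <- ids
  if (transpose) m <- t(m)
  m
}

#' Write a methylation matrix as delimited text
#'
#' @param betas Samples-by-sites matrix with dimnames.
#' @param path Output path.
#' @param delim Field delimiter.
#' @export
write_beta_matrix <- function(betas, path, delim = ",") {
  df <- data.frame(sample_id = rownames(betas), betas,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(.fmt_df(df), path, sep = delim, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read sample metadata from CSV
#'
#' Requires a `sample_id` column and at least one of `age_true` /
#' `age_reported`; any further columns (sex, tissue, population, class,
#' ...) are preserved as given.
#'
#' @param path File path.
#' @param delim Field delimiter.
#' @return Data frame, one row per sample.
#' @export
read_metadata <- function(path, delim = ",") {
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df))
    stop("metadata must contain a `sample_id` column", call. = FALSE)
  if (!any(c("age_true", "age_reported") %in% names(df)))
    stop("metadata must contain `age_true` or `age_reported`",
         call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id(s) in metadata", call. = FALSE)
  df
}

#' Write sample metadata as CSV
#' @param meta Data frame with `sample_id`.
#' @param path Output path.
#' @param delim Field delimiter.
#' @export
write_metadata <- function(meta, path, delim = ",") {
  utils::write.table(.fmt_df(meta), path, sep = delim, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read / write a site keep-list (one site ID per line)
#' @param path File path.
#' @return Character vector of site IDs.
#' @export
read_keep_list <- function(path) {
  x <- readLines(path)
  x[nzchar(trimws(x))]
}

#' @rdname read_keep_list
#' @param sites Character vector of site IDs.
#' @export
write_keep_list <- function(sites, path) {
  writeLines(sites, path)
  invisible(path)
}

#' Save a fitted clock as JSON
#'
#' Serializes intercept, coefficients, hyperparameters, standardization
#' info and training provenance with full numeric precision, so a
#' reloaded clock reproduces predictions exactly.
#'
#' @param model A `clock_model`.
#' @param path Output path.
#' @export
save_clock <- function(model, path) {
  stopifnot(inherits(model, "clock_model"))
  payload <- list(
    schema_version = CLOCK_SCHEMA_VERSION,
    intercept = model$intercept,
    alpha = model$alpha,
    lambda = model$lambda,
    coefficients = as.list(model$coefficients),
    standardization = list(
      center = as.list(model$standardization$center),
      scale = as.list(model$standardization$scale),
      note = model$standardization$note
    ),
    training_info = model$training_info
  )
  # I(17) significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load a clock saved with [save_clock()]
#' @param path JSON file path.
#' @return A `clock_model`.
#' @export
load_clock <- function(path) {
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                      error = function(e)
                        stop("cannot parse clock file: ",
                             conditionMessage(e), call. = FALSE))
  ver <- payload$schema_version
  if (is.null(ver) || !identical(ver, CLOCK_SCHEMA_VERSION))
    stop("clock schema version mismatch: file has `",
         if (is.null(ver)) "<none>" else ver, "`, package expects `",
         CLOCK_SCHEMA_VERSION, "`", call. = FALSE)
  cf <- unlist(payload$coefficients)
  if (is.null(cf)) cf <- stats::setNames(numeric(0), character(0))
  structure(list(
    intercept = payload$intercept,
    coefficients = cf,
    alpha = payload$alpha,
    lambda = payload$lambda,
    standardization = list(
      center = unlist(payload$standardization$center),
      scale = unlist(payload$standardization$scale),
      note = payload$standardization$note
    ),
    training_info = payload$training_info
  ), class = "clock_model")
}

#' Export / import clock coefficients as a two-column CSV
#'
#' Writes `site_id,weight` rows plus an `(Intercept)` row, the common
#' interchange format for published clock coefficient tables.
#'
#' @param model A `clock_model`.
#' @param path CSV path.
#' @export
write_clock_coefs <- function(model, path) {
  df <- data.frame(
    site_id = c("(Intercept)", names(model$coefficients)),
    weight = c(model$intercept, unname(model$coefficients)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_clock_coefs
#' @return `read_clock_coefs()` returns a list with `intercept` and a
#'   named `coefficients` vector.
#' @export
read_clock_coefs <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = ",",
                          stringsAsFactors = FALSE)
  ic <- df$site_id == "(Intercept)"
  list(intercept = df$weight[ic][1],
       coefficients = stats::setNames(df$weight[!ic], df$site_id[!ic]))
}

#' Load / save a simulation config as YAML
#'
#' @param path YAML file path.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(sim_config, y)
}

#' @rdname read_sim_config
#' @param config A [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Write an experiment results table with a provenance sidecar
#'
#' Saves the tidy results as CSV and a JSON sidecar recording the
#' package version, seed and any extra provenance fields, so a run can
#' be reproduced from its outputs alone.
#'
#' @param results Data frame from one of the `run_*` experiment
#'   harnesses.
#' @param dir Output directory (created if missing).
#' @param name Basename for the two files.
#' @param provenance Named list of extra provenance fields (e.g. the
#'   config and master seed).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(results, dir, name = "experiment",
                          provenance = list()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, paste0(name, ".csv"))
  js <- file.path(dir, paste0(name, "_provenance.json"))
  utils::write.table(results, csv, sep = ",", row.names = FALSE,
                     quote = FALSE)
  prov <- c(list(package = "wildclockr",
                 version = as.character(utils::packageVersion("wildclockr")),
                 written = format(Sys.time(), tz = "UTC")),
            provenance)
  jsonlite::write_json(prov, js, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(c(csv = csv, provenance = js))
}
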