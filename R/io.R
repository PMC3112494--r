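#' Reading and writing densities, models and model spaces
#'
#' Structured artifacts are JSON (UTF-8, matrices row-major, floats carrying
#' 17 significant digits so that write-then-read round-trips exactly);
#' tabular data are CSV. A density file is an object
#' `{"mean": [...], "precision": [[...]] or "covariance": [[...]],
#' "labels": [...]}`; a full-model file is
#' `{"prior": <density>, "posterior": <density>, "free_energy": <number>,
#' "meta": {...}}`.
#'
#' @param x object to serialize.
#' @param file path to read or write.
#' @return readers return the reconstructed object; writers return `file`
#'   invisibly.
#' @name bmr_io
NULL

# jsonlite serializes row-major (a matrix becomes an array of row arrays);
# 17 significant digits guarantee exact double round-trips
.write_json <- function(x, file) {
  jsonlite::write_json(x, file, digits = I(17), auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  invisible(file)
}

.read_json <- function(file) {
  if (!file.exists(file))
    stop(sprintf("file not found: %s", file), call. = FALSE)
  tryCatch(jsonlite::read_json(file, simplifyVector = TRUE),
           error = function(e)
             stop(sprintf("malformed JSON in %s: %s", file,
                          conditionMessage(e)), call. = FALSE))
}

.require_field <- function(obj, field, file) {
  if (is.null(obj[[field]]))
    stop(sprintf("missing field '%s' in %s", field, file), call. = FALSE)
  obj[[field]]
}

.density_to_list <- function(d) {
  out <- list(mean = d$mean)
  if (any(d$fixed)) out$covariance <- d$cov else out$precision <- d$prec
  if (!is.null(d$labels)) out$labels <- d$labels
  out
}

.density_from_list <- function(obj, file = "<density>") {
  mean <- as.numeric(.require_field(obj, "mean", file))
  labels <- if (!is.null(obj$labels)) as.character(obj$labels)
  as_mat <- function(m, name) {
    m <- as.matrix(m)
    if (!is.numeric(m) || nrow(m) != length(mean) || ncol(m) != length(mean))
      stop(sprintf("field '%s' in %s must be a %d x %d numeric matrix",
                   name, file, length(mean), length(mean)), call. = FALSE)
    m
  }
  if (!is.null(obj$precision))
    gaussian_density(mean, precision = as_mat(obj$precision, "precision"),
                     labels = labels)
  else if (!is.null(obj$covariance))
    gaussian_density(mean, covariance = as_mat(obj$covariance, "covariance"),
                     labels = labels)
  else stop(sprintf("density in %s needs a 'precision' or 'covariance' field",
                    file), call. = FALSE)
}

#' @rdname bmr_io
#' @export
write_density <- function(x, file) {
  stopifnot(inherits(x, "bmr_density"))
  .write_json(.density_to_list(x), file)
}

#' @rdname bmr_io
#' @export
read_density <- function(file) .density_from_list(.read_json(file), file)

#' @rdname bmr_io
#' @export
write_full_model <- function(x, file) {
  stopifnot(inherits(x, "bmr_full_model"))
  .write_json(list(prior = .density_to_list(x$prior),
                   posterior = .density_to_list(x$posterior),
                   free_energy = x$free_energy,
                   meta = x$meta), file)
}

#' @rdname bmr_io
#' @export
read_full_model <- function(file) {
  obj <- .read_json(file)
  for (f in c("prior", "posterior"))
    if (is.null(obj[[f]]))
      stop(sprintf("missing field '%s' in %s", f, file), call. = FALSE)
  fe <- if (is.null(obj$free_energy)) 0 else as.numeric(obj$free_energy)
  meta <- if (is.null(obj$meta)) list() else obj$meta
  full_model(.density_from_list(obj$prior, file),
             .density_from_list(obj$posterior, file),
             free_energy = fe, meta = meta)
}

#' @rdname bmr_io
#' @param base_prior full-model prior the switch space or family refers to
#'   (index sets in the file are interpreted against it).
#' @export
read_switch_space <- function(file, base_prior) {
  obj <- .read_json(file)
  switchable <- as.integer(.require_field(obj, "switchable", file))
  gamma <- as.numeric(.require_field(obj, "gamma", file))
  pairs <- NULL
  if (!is.null(obj$pairs)) {
    pm <- obj$pairs
    if (is.matrix(pm)) pairs <- lapply(seq_len(nrow(pm)), function(i)
      as.integer(pm[i, ]))
    else pairs <- lapply(pm, as.integer)
  }
  switch_space(base_prior, switchable = switchable, gamma = gamma,
               pairs = pairs)
}

#' @rdname bmr_io
#' @export
write_switch_space <- function(x, file) {
  stopifnot(inherits(x, "bmr_switch_space"))
  .write_json(list(switchable = x$switchable, gamma = x$gamma,
                   pairs = x$pairs[lengths(x$pairs) > 1L]), file)
}

#' Read a declarative prior-family specification
#'
#' Family files are JSON objects with a `type` of `"shared_mean_variance"`
#' (Fig.-1-style family: one shared prior mean and one shared prior variance
#' over an index set) or `"per_param_variance"` (relevance determination:
#' one variance per indexed parameter; optional `gamma` reference scale), and
#' an `indices` array.
#'
#' @param file path to the family JSON.
#' @param base_prior the full model's prior.
#' @return a [prior_family()].
#' @export
read_family <- function(file, base_prior) {
  obj <- .read_json(file)
  type <- .require_field(obj, "type", file)
  indices <- as.integer(.require_field(obj, "indices", file))
  switch(as.character(type),
    shared_mean_variance = family_shared_mean_variance(base_prior, indices),
    per_param_variance = family_per_param_variance(
      base_prior, indices, gamma = if (!is.null(obj$gamma))
        as.numeric(obj$gamma)),
    stop(sprintf("unknown family type '%s' in %s", type, file),
         call. = FALSE))
}

#' Read GLM data from CSV
#'
#' The design CSV has observations as rows and a header row of column names.
#' The response is taken from the named `response` column; an optional
#' `groups` column carries noise-group indices (absent means one group).
#' Remaining columns form the design matrix.
#'
#' @param file path to the CSV.
#' @param response name of the response column (default `"y"`).
#' @param groups name of the noise-group column, or `NULL`.
#' @return a [glm_data()].
#' @export
read_glm_csv <- function(file, response = "y", groups = NULL) {
  if (!file.exists(file))
    stop(sprintf("file not found: %s", file), call. = FALSE)
  df <- utils::read.csv(file, check.names = FALSE)
  if (!response %in% names(df))
    stop(sprintf("response column '%s' not found in %s", response, file),
         call. = FALSE)
  y <- df[[response]]
  part <- rep(1L, length(y))
  drop <- response
  if (!is.null(groups)) {
    if (!groups %in% names(df))
      stop(sprintf("group column '%s' not found in %s", groups, file),
           call. = FALSE)
    part <- as.integer(df[[groups]])
    drop <- c(drop, groups)
  }
  X <- as.matrix(df[setdiff(names(df), drop)])
  glm_data(y, X, part)
}

#' @rdname read_glm_csv
#' @param data a [glm_data()] to write; the response is written as column
#'   `y` and the groups (when more than one) as column `group`.
#' @export
write_glm_csv <- function(data, file) {
  stopifnot(inherits(data, "bmr_glm_data"))
  X <- data$X
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  df <- data.frame(y = data$y, X, check.names = FALSE)
  if (data$n_groups > 1L) df$group <- data$partition
  utils::write.csv(format(df, digits = 17, trim = TRUE), file,
                   row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read or write a network time series as CSV (bins x nodes, header = node
#' names)
#'
#' @param file path to the CSV.
#' @return `read_series_csv` returns a numeric matrix.
#' @export
read_series_csv <- function(file) {
  if (!file.exists(file))
    stop(sprintf("file not found: %s", file), call. = FALSE)
  as.matrix(utils::read.csv(file, check.names = FALSE))
}

#' @rdname read_series_csv
#' @param series numeric matrix of observations.
#' @export
write_series_csv <- function(series, file) {
  series <- as.matrix(series)
  if (is.null(colnames(series)))
    colnames(series) <- paste0("node_", seq_len(ncol(series)))
  utils::write.csv(format(as.data.frame(series), digits = 17, trim = TRUE),
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
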