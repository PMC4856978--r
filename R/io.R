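# ---- delimited-text readers/writers and JSON model serialization ----------

.read_table_checked <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty file: ", path)
  cells <- strsplit(lines, delimiter, fixed = TRUE)
  widths <- lengths(cells)
  if (any(widths != widths[1L])) {
    bad <- which(widths != widths[1L])[1L]
    stop(sprintf("ragged row in %s: line %d has %d fields, expected %d",
                 path, bad, widths[bad], widths[1L]))
  }
  cells
}

#' Read a delimited expression matrix
#'
#' Expects a header row; the first column holds observation identifiers and
#' the remaining columns are features (use `transpose = TRUE` for
#' feature-by-sample files such as GEO series matrices). Cells that do not
#' parse as numbers (including `"NA"`) become missing values; the count of
#' such cells is reported via `message()`.
#'
#' @param path Path to a delimited text file.
#' @param delimiter Field separator (default tab).
#' @param transpose If `TRUE`, the file is features x observations and is
#'   transposed after reading.
#' @return A list with `values` (numeric matrix, observations x features),
#'   `observation_ids` and `feature_ids`.
#' @export
read_expression <- function(path, delimiter = "\t", transpose = FALSE) {
  cells <- .read_table_checked(path, delimiter)
  header <- cells[[1L]]
  if (length(header) < 2L) stop("expected at least one id column and one data column")
  col_ids <- header[-1L]
  body <- cells[-1L]
  row_ids <- vapply(body, `[[`, character(1), 1L)
  raw <- do.call(rbind, lapply(body, function(r) r[-1L]))
  suppressWarnings(values <- matrix(as.numeric(raw), nrow = length(row_ids)))
  n_bad <- sum(is.na(values) & !is.na(raw) & toupper(raw) != "NA" & raw != "")
  if (n_bad > 0) message(sprintf("read_expression: %d non-numeric cell(s) set to missing", n_bad))
  dimnames(values) <- list(row_ids, col_ids)
  if (transpose) values <- t(values)
  if (anyDuplicated(rownames(values))) {
    stop("duplicate observation ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate feature ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  }
  list(values = values, observation_ids = rownames(values),
       feature_ids = colnames(values))
}

#' Write an expression matrix as delimited text
#'
#' Inverse of [read_expression()]: observations x features with a leading
#' id column.
#'
#' @param values Numeric matrix with dimnames.
#' @param path Output path.
#' @param delimiter Field separator (default tab).
#' @export
write_expression <- function(values, path, delimiter = "\t") {
  df <- data.frame(observation_id = rownames(values), values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# shared reader for two-column (observation id, value) metadata files
.read_two_col <- function(path, delimiter, what, observation_ids) {
  cells <- .read_table_checked(path, delimiter)
  body <- cells[-1L]  # header assumed
  ids <- vapply(body, `[[`, character(1), 1L)
  vals <- vapply(body, `[[`, character(1), 2L)
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate observation id in %s file: %s", what,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  missing_ids <- setdiff(observation_ids, ids)
  if (length(missing_ids)) {
    stop(sprintf("%s file lacks observation id(s): %s", what,
                 paste(utils::head(missing_ids, 5), collapse = ", ")))
  }
  vals[match(observation_ids, ids)]
}

#' Read observation times and rescale to the unit interval
#'
#' Reads a two-column delimited file (header, then observation id and time
#' in native units), aligns rows to `observation_ids` by id (order in the
#' file is irrelevant), reduces modulo `period` and divides by it, so e.g.
#' 26 h with a 24 h period becomes 2/24.
#'
#' @param path Path to the metadata file.
#' @param observation_ids Ids the result must align to, each present
#'   exactly once in the file.
#' @param period Cycle length in the file's units (default 24).
#' @param delimiter Field separator (default tab).
#' @return Numeric vector of times in `[0, 1)`, aligned to
#'   `observation_ids`.
#' @export
read_times <- function(path, observation_ids, period = 24, delimiter = "\t") {
  vals <- .read_two_col(path, delimiter, "time", observation_ids)
  times <- suppressWarnings(as.numeric(vals))
  if (anyNA(times)) {
    stop("non-numeric time value(s) for observation(s): ",
         paste(utils::head(observation_ids[is.na(times)], 5), collapse = ", "))
  }
  (times %% period) / period
}

#' Read group labels aligned to observation ids
#'
#' @inheritParams read_times
#' @return Character vector of group labels aligned to `observation_ids`.
#' @export
read_groups <- function(path, observation_ids, delimiter = "\t") {
  .read_two_col(path, delimiter, "group", observation_ids)
}

.schema_version <- "1.0"

.curve_to_list <- function(curve) {
  list(coef = curve$coef, harmonics = curve$harmonics, n_knots = curve$n_knots,
       lambda = curve$lambda, edf = curve$edf, n = curve$n)
}

.curve_from_list <- function(x) {
  .new_periodic_curve(as.numeric(x$coef), as.integer(x$harmonics),
                      as.integer(x$n_knots), as.numeric(x$lambda),
                      as.numeric(x$edf), as.integer(x$n))
}

#' Save a trained model as JSON
#'
#' Serializes a `"ct_model"` to a versioned, plain-JSON document readable
#' by any JSON parser. Sparse loadings are stored as index/value pairs;
#' numbers are written with 17 significant digits so that a reloaded model
#' reproduces the original's predictions bit for bit.
#'
#' @param model A `"ct_model"`.
#' @param path Output path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ct_model"))
  V <- model$loadings
  loadings <- lapply(seq_len(ncol(V)), function(k) {
    idx <- which(V[, k] != 0)
    list(index = idx, value = V[idx, k])
  })
  doc <- list(
    schema_version = .schema_version,
    parameters = model$parameters,
    n_obs = model$n_obs,
    feature_ids = model$feature_ids,
    predictor_features = model$predictor_features,
    n_features = length(model$feature_ids),
    loadings = loadings,
    singular_values = model$singular_values,
    variance_explained = model$variance_explained,
    spc_densities = lapply(model$spc_densities, function(d) {
      list(mean_curve = .curve_to_list(d$mean_curve), variance = d$variance,
           n_used = d$n_used, feature_id = d$feature_id)
    })
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17), null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path Path to the JSON model file.
#' @return A `"ct_model"` whose predictions are identical to the saved
#'   model's.
#' @export
load_model <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop("malformed model file: ", conditionMessage(e), call. = FALSE)
                  })
  required <- c("schema_version", "parameters", "feature_ids", "loadings",
                "spc_densities", "predictor_features")
  absent <- setdiff(required, names(doc))
  if (length(absent)) {
    stop("model file lacks required field(s): ", paste(absent, collapse = ", "))
  }
  if (!identical(doc$schema_version, .schema_version)) {
    stop(sprintf("model schema version '%s' not supported (expected '%s')",
                 doc$schema_version, .schema_version))
  }
  feature_ids <- as.character(unlist(doc$feature_ids))
  p <- length(feature_ids)
  m <- length(doc$loadings)
  V <- matrix(0, p, m, dimnames = list(feature_ids, paste0("SPC", seq_len(m))))
  for (k in seq_len(m)) {
    idx <- as.integer(unlist(doc$loadings[[k]]$index))
    V[idx, k] <- as.numeric(unlist(doc$loadings[[k]]$value))
  }
  params <- doc$parameters
  structure(
    list(loadings = V,
         spc_densities = lapply(doc$spc_densities, function(d) {
           structure(list(mean_curve = .curve_from_list(d$mean_curve),
                          variance = as.numeric(d$variance),
                          n_used = as.integer(d$n_used),
                          feature_id = as.character(d$feature_id)),
                     class = "time_density")
         }),
         feature_ids = feature_ids,
         predictor_features = as.character(unlist(doc$predictor_features)),
         parameters = list(sumabsv = as.numeric(params$sumabsv),
                           n_spc = as.integer(params$n_spc),
                           m = as.integer(params$m),
                           n_knots = as.numeric(params$n_knots),
                           period_units = as.numeric(params$period_units)),
         singular_values = as.numeric(unlist(doc$singular_values)),
         variance_explained = as.numeric(unlist(doc$variance_explained)),
         n_obs = as.integer(doc$n_obs)),
    class = "ct_model"
  )
}

#' Write a prediction table as TSV
#'
#' @param predictions Data frame as returned by [predict.ct_model()].
#' @param path Output path.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.table(predictions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
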