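#' Assemble a time-stamped measurement matrix
#'
#' Bundles a numeric matrix of observations-by-features with the value of the
#' periodic variable (e.g. circadian time) at which each observation was
#' taken. Times given in native units (say hours) are reduced modulo `period`
#' and rescaled to the unit interval; all downstream computation works on
#' `[0, 1)` with time 0 identified with time 1.
#'
#' @param values Numeric matrix, n observations x p features. Missing entries
#'   (`NA`) are allowed and handled per feature downstream.
#' @param times Numeric vector of length n: the periodic-variable value of
#'   each observation, in units of `period`.
#' @param period Positive scalar giving the length of one cycle in the units
#'   of `times` (default 1, i.e. times already on the unit scale).
#' @param feature_ids,observation_ids Optional identifier vectors; default to
#'   the matrix dimnames, or generated identifiers when absent. Feature ids
#'   must be unique.
#'
#' @return An object of class `"time_matrix"`: a list with elements `values`
#'   (dimnamed matrix), `times` (in `[0, 1)`), `feature_ids`,
#'   `observation_ids` and `period`.
#' @examples
#' x <- matrix(rnorm(24), nrow = 12)
#' tm <- time_matrix(x, times = rep(seq(0, 22, by = 4), 2), period = 24)
#' range(tm$times)
#' @export
time_matrix <- function(values, times, period = 1,
                        feature_ids = colnames(values),
                        observation_ids = rownames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(times) || length(times) != nrow(values)) {
    stop("`times` must be a numeric vector with one entry per row of `values`")
  }
  if (anyNA(times)) stop("`times` must not contain missing values")
  if (!is.numeric(period) || length(period) != 1L || period <= 0) {
    stop("`period` must be a single positive number")
  }
  times <- (times %% period) / period
  # guard against floating-point landing exactly on 1
  times[times >= 1] <- 0
  if (is.null(feature_ids)) feature_ids <- sprintf("feature%d", seq_len(ncol(values)))
  if (is.null(observation_ids)) observation_ids <- sprintf("obs%d", seq_len(nrow(values)))
  feature_ids <- as.character(feature_ids)
  observation_ids <- as.character(observation_ids)
  if (length(feature_ids) != ncol(values)) stop("`feature_ids` length must equal ncol(values)")
  if (length(observation_ids) != nrow(values)) stop("`observation_ids` length must equal nrow(values)")
  if (anyDuplicated(feature_ids)) {
    stop("duplicate feature ids: ", paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  }
  dimnames(values) <- list(observation_ids, feature_ids)
  structure(
    list(values = values, times = times, feature_ids = feature_ids,
         observation_ids = observation_ids, period = period),
    class = "time_matrix"
  )
}

#' @export
print.time_matrix <- function(x, ...) {
  cat(sprintf("<time_matrix> %d observations x %d features, period %g\n",
              nrow(x$values), ncol(x$values), x$period))
  cat(sprintf("  times: %d distinct values in [0, 1)\n", length(unique(x$times))))
  n_missing <- sum(is.na(x$values))
  if (n_missing > 0) cat(sprintf("  missing entries: %d\n", n_missing))
  invisible(x)
}

#' @export
dim.time_matrix <- function(x) dim(x$values)

# row subset preserving metadata (used by the CV harness)
tm_subset <- function(data, idx) {
  time_matrix(data$values[idx, , drop = FALSE], data$times[idx], period = 1,
              feature_ids = data$feature_ids,
              observation_ids = data$observation_ids[idx])
}

# wrap to [0, 1): `x %% 1` alone can return exactly 1 for a tiny negative x
.wrap01 <- function(x) {
  x <- x %% 1
  x[x >= 1] <- 0
  x
}

as_time_matrix <- function(x) {
  if (inherits(x, "time_matrix")) return(x)
  stop("expected a `time_matrix`; see ?time_matrix")
}
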