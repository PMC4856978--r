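# ---- molecular-timetable comparator ---------------------------------------

#' Train a molecular-timetable model
#'
#' Comparator method for sparse-component prediction: selects
#' "time-indicating" features that (a) correlate strongly with a cosine of
#' the system's period at some phase (periodicity) and (b) vary enough
#' across training observations (standard deviation; used instead of the
#' coefficient of variation, which is meaningless for data containing
#' negative values, e.g. log-ratios). Each retained feature is summarized
#' by its peak time, the phase maximizing that correlation.
#'
#' @param data A [time_matrix()]; missing values are not supported by this
#'   method.
#' @param min_periodicity Minimum cosine correlation to retain a feature
#'   (default 0.8).
#' @param min_sd Minimum standard deviation; by default the 90th percentile
#'   of all feature standard deviations.
#' @param n_phase Number of candidate phases for peak-time estimation
#'   (default 200, plus local refinement).
#' @return An object of class `"mt_model"`: data.frame `features`
#'   (feature_id, peak_time, periodicity, variability, mean), plus the
#'   thresholds used.
#' @examples
#' sim <- default_benchmark(seed = 1)
#' mt <- mt_train(sim$data)
#' nrow(mt$features)
#' @export
mt_train <- function(data, min_periodicity = 0.8, min_sd = NULL, n_phase = 200L) {
  data <- as_time_matrix(data)
  if (anyNA(data$values)) {
    stop("the molecular-timetable method does not support missing values")
  }
  sds <- apply(data$values, 2L, stats::sd)
  means <- colMeans(data$values)
  if (is.null(min_sd)) min_sd <- stats::quantile(sds, 0.9, names = FALSE)
  # grid correlations for all features in one pass, then refine per feature
  phis <- (seq_len(n_phase) - 1L) / n_phase
  templates <- cos(2 * pi * outer(data$times, phis, "-"))
  variable <- sds > 0
  cors <- matrix(-Inf, ncol(data$values), n_phase)
  if (any(variable)) {
    cc <- suppressWarnings(stats::cor(data$values[, variable, drop = FALSE], templates))
    cc[is.na(cc)] <- -Inf
    cors[variable, ] <- cc
  }
  periodicity <- numeric(ncol(data$values))
  peak_time <- rep(NA_real_, ncol(data$values))
  h <- 1 / n_phase
  for (j in which(variable)) {
    i <- which.max(cors[j, ])
    y <- data$values[, j]
    obj <- function(phi) {
      r <- suppressWarnings(stats::cor(y, cos(2 * pi * (data$times - phi %% 1))))
      if (is.na(r)) -Inf else r
    }
    opt <- stats::optimize(obj, lower = phis[i] - h, upper = phis[i] + h,
                           maximum = TRUE, tol = 1e-7)
    if (opt$objective >= cors[j, i]) {
      periodicity[j] <- opt$objective
      peak_time[j] <- .wrap01(opt$maximum)
    } else {
      periodicity[j] <- cors[j, i]
      peak_time[j] <- phis[i]
    }
  }
  keep <- periodicity >= min_periodicity & sds >= min_sd & !is.na(peak_time)
  if (!any(keep)) {
    stop(sprintf(
      "no feature passes both thresholds (min_periodicity = %g, min_sd = %g)",
      min_periodicity, min_sd))
  }
  features <- data.frame(
    feature_id = data$feature_ids[keep],
    peak_time = unname(peak_time[keep]),
    periodicity = unname(periodicity[keep]),
    variability = unname(sds[keep]),
    mean = unname(means[keep]),
    stringsAsFactors = FALSE
  )
  rownames(features) <- NULL
  structure(
    list(features = features,
         thresholds = list(min_periodicity = min_periodicity, min_sd = min_sd),
         period_units = data$period),
    class = "mt_model"
  )
}

#' @export
print.mt_model <- function(x, ...) {
  cat(sprintf("<mt_model> %d time-indicating features (min periodicity %.2f, min sd %.3g)\n",
              nrow(x$features), x$thresholds$min_periodicity, x$thresholds$min_sd))
  invisible(x)
}

#' Predict time with a molecular-timetable model
#'
#' Standardizes the test observation per feature by the training mean and
#' standard deviation, then finds the time whose cosine templates —
#' `cos(2*pi*(t - peak_time_j))` across the retained features j — correlate
#' best with the standardized values (grid of `n_grid` candidate times plus
#' local refinement). The achieved correlation is returned in the
#' `log_likelihood` slot; note this is a correlation, not a
#' log-likelihood, a deliberate difference from [predict.ct_model()]. With
#' a single retained feature a correlation is undefined, so the negative
#' squared distance to the template is maximized instead.
#'
#' @param model An `"mt_model"`.
#' @param w Named numeric vector (or 1-row matrix) containing a value for
#'   every model feature; no missing values.
#' @param n_grid Number of candidate times (default 200).
#' @return A `"ct_prediction"` with `time_hat` in `[0, 1)` and the match
#'   score in `log_likelihood`.
#' @export
mt_predict <- function(model, w, n_grid = 200L) {
  stopifnot(inherits(model, "mt_model"))
  if (!is.null(dim(w))) w <- drop(as.matrix(w)[1L, ])
  feats <- model$features
  if (!is.null(names(w))) {
    miss <- setdiff(feats$feature_id, names(w))
    if (length(miss)) {
      stop("test observation lacks model feature(s): ",
           paste(utils::head(miss, 5), collapse = ", "))
    }
    w <- w[feats$feature_id]
  } else if (length(w) != nrow(feats)) {
    stop(sprintf("unnamed test vector has %d values but the model retains %d features",
                 length(w), nrow(feats)))
  }
  if (anyNA(w)) stop("test observation has missing values for model features")
  z <- (w - feats$mean) / feats$variability
  score <- if (length(z) >= 2L) {
    function(t) {
      r <- suppressWarnings(stats::cor(z, cos(2 * pi * ((t %% 1) - feats$peak_time))))
      if (is.na(r)) -Inf else r
    }
  } else {
    function(t) -(z - cos(2 * pi * ((t %% 1) - feats$peak_time)))^2
  }
  grid <- (seq_len(n_grid) - 1L) / n_grid
  vals <- vapply(grid, score, numeric(1))
  i <- which.max(vals)
  h <- 1 / n_grid
  opt <- stats::optimize(score, lower = grid[i] - h, upper = grid[i] + h,
                         maximum = TRUE, tol = 1e-7)
  if (opt$objective >= vals[i]) {
    t_hat <- .wrap01(opt$maximum)
    best <- opt$objective
  } else {
    t_hat <- grid[i]
    best <- vals[i]
  }
  structure(list(time_hat = t_hat, log_likelihood = best, curve = NULL),
            class = "ct_prediction")
}

#' Randomly subset a molecular-timetable model
#'
#' Retains a uniform random subset of `k` of the model's time-indicating
#' features (reproducible via `seed`), mirroring accuracy-versus-gene-count
#' comparisons. With `k` equal to the full feature count the model is
#' returned unchanged.
#'
#' @param model An `"mt_model"`.
#' @param k Number of features to keep, between 1 and the feature count.
#' @param seed Integer seed for the subset draw (the global RNG state is
#'   left untouched).
#' @return An `"mt_model"` with `k` features.
#' @export
mt_random_subset <- function(model, k, seed) {
  stopifnot(inherits(model, "mt_model"))
  n <- nrow(model$features)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > n) {
    stop(sprintf("`k` must be between 1 and %d (the number of model features)", n))
  }
  k <- as.integer(k)
  if (k == n) return(model)
  idx <- withr::with_seed(as.integer(seed), sort(sample.int(n, k)))
  model$features <- model$features[idx, , drop = FALSE]
  rownames(model$features) <- NULL
  model
}
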