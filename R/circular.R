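# ---- circular error statistics and leave-one-group-out CV -----------------

#' Signed circular error between true and predicted periodic values
#'
#' Computes `t_hat - t` wrapped to the shortest arc:
#' the raw difference if it lies in `[-0.5, 0.5]`, plus 1 if below -0.5,
#' minus 1 if above 0.5. The signed error is therefore always in
#' `[-0.5, 0.5]` and the absolute error in `[0, 0.5]`. At a raw difference
#' of exactly +/-0.5 both wrappings are equidistant; the unwrapped value is
#' kept, so the signed error is +/-0.5 as given.
#'
#' @param t,t_hat Numeric vectors in `[0, 1)` (recycled to common length).
#' @return Numeric vector of signed errors; take `abs()` for absolute
#'   errors.
#' @examples
#' circular_error(0.9, 0.1)  # wraps to +0.2
#' circular_error(0.1, 0.9)  # wraps to -0.2
#' @export
circular_error <- function(t, t_hat) {
  if (any(t < 0 | t >= 1, na.rm = TRUE) || any(t_hat < 0 | t_hat >= 1, na.rm = TRUE)) {
    stop("`t` and `t_hat` must lie in [0, 1); rescale by the period first")
  }
  e <- t_hat - t
  e[e < -0.5] <- e[e < -0.5] + 1
  e[e > 0.5] <- e[e > 0.5] - 1
  e
}

#' Mean absolute circular error
#'
#' Arithmetic mean of `abs(circular_error(t, t_hat))`; always in
#' `[0, 0.5]`. A predictor guessing uniformly at random scores 0.25 on the
#' unit scale (6 h on a 24 h clock), the reference point against which any
#' real predictor should be judged.
#'
#' @param t,t_hat Numeric vectors in `[0, 1)` of equal length, nonempty.
#' @return A single number in `[0, 0.5]`.
#' @export
circular_mae <- function(t, t_hat) {
  if (!length(t) || !length(t_hat)) stop("need at least one (t, t_hat) pair")
  mean(abs(circular_error(t, t_hat)))
}

#' Leave-one-group-out cross-validation
#'
#' For each level of `groups` (e.g. organs), trains a predictor on all other
#' groups' observations and predicts the time of each held-out observation;
#' no information from the held-out group reaches training. Repeated for
#' every row of `param_grid`, pooling predictions across folds.
#'
#' Models are shared across grid rows that differ only in `n_spc` (the
#' number of components only matters at prediction time), so the grid costs
#' one training pass per distinct `sumabsv` per fold; results are identical
#' to training each grid point separately.
#'
#' @param data A [time_matrix()].
#' @param groups Vector of group labels, one per observation; at least two
#'   distinct groups.
#' @param param_grid Data frame with columns `sumabsv` and `n_spc`, one row
#'   per parameter combination (default `sumabsv = 2, n_spc = 2`).
#' @param m,n_knots Passed to [ct_train()].
#' @return A list of `"ct_cv"` objects, one per grid row, each with
#'   `per_observation` (data.frame: observation_id, group, time_true,
#'   time_hat, signed_error, log_likelihood), `per_group_mae` (named
#'   vector), `overall_mae`, and `parameters`.
#' @examples
#' sim <- default_benchmark(seed = 1)
#' cv <- leave_one_group_out_cv(sim$data, sim$groups,
#'                              param_grid = data.frame(sumabsv = 3, n_spc = 2))
#' cv[[1]]$overall_mae
#' @export
leave_one_group_out_cv <- function(data, groups,
                                   param_grid = data.frame(sumabsv = 2, n_spc = 2),
                                   m = 12, n_knots = 3) {
  data <- as_time_matrix(data)
  groups <- as.character(groups)
  if (length(groups) != nrow(data$values)) {
    stop("`groups` must have one label per observation")
  }
  levels <- unique(groups)
  if (length(levels) < 2L) stop("need at least 2 distinct groups for leave-one-group-out CV")
  if (!all(c("sumabsv", "n_spc") %in% names(param_grid))) {
    stop("`param_grid` must have columns `sumabsv` and `n_spc`")
  }

  # one model per (fold, sumabsv); n_spc applied at prediction time
  sumabsv_values <- unique(param_grid$sumabsv)
  max_nspc <- max(param_grid$n_spc)
  models <- list()
  for (sv in sumabsv_values) {
    for (g in levels) {
      train_idx <- which(groups != g)
      fold <- tm_subset(data, train_idx)
      models[[paste(sv, g)]] <- tryCatch(
        ct_train(fold, sumabsv = sv, n_spc = max_nspc, m = m, n_knots = n_knots),
        error = function(e) {
          stop(sprintf("fold holding out group '%s': %s", g, conditionMessage(e)),
               call. = FALSE)
        })
    }
  }

  out <- vector("list", nrow(param_grid))
  for (r in seq_len(nrow(param_grid))) {
    sv <- param_grid$sumabsv[r]
    nspc <- param_grid$n_spc[r]
    rows <- list()
    for (g in levels) {
      test_idx <- which(groups == g)
      model <- models[[paste(sv, g)]]
      pred <- predict(model, data$values[test_idx, , drop = FALSE], n_spc = nspc)
      rows[[g]] <- data.frame(
        observation_id = data$observation_ids[test_idx],
        group = g,
        time_true = data$times[test_idx],
        time_hat = pred$time_hat,
        signed_error = circular_error(data$times[test_idx], pred$time_hat),
        log_likelihood = pred$log_likelihood,
        stringsAsFactors = FALSE
      )
    }
    per_obs <- do.call(rbind, rows)
    rownames(per_obs) <- NULL
    abs_err <- abs(per_obs$signed_error)
    per_group <- vapply(split(abs_err, per_obs$group), mean, numeric(1))
    out[[r]] <- structure(
      list(per_observation = per_obs,
           per_group_mae = per_group[levels],
           overall_mae = mean(abs_err),
           parameters = list(sumabsv = sv, n_spc = nspc, m = m, n_knots = n_knots)),
      class = "ct_cv"
    )
  }
  out
}

#' @export
print.ct_cv <- function(x, ...) {
  p <- x$parameters
  cat(sprintf("<ct_cv> sumabsv = %s, n_spc = %d: overall MAE = %.4f (unit scale)\n",
              format(p$sumabsv), p$n_spc, x$overall_mae))
  cat("  per-group MAE:\n")
  print(round(x$per_group_mae, 4))
  invisible(x)
}
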