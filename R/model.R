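# ---- training and maximum-likelihood time prediction ----------------------

#' Train a circadian time predictor
#'
#' Runs the full training pipeline: (1) fit each feature's time-dependent
#' mean curve and residual variance ([fit_time_densities()]); (2) build the
#' noise-scaled pattern matrix ([build_pattern_matrix()]); (3) extract its
#' sparse principal components ([pmd()]); (4) project the training data into
#' component space (`X %*% V`, with an available-case rule for missing
#' training entries); (5) fit the time-dependent mean and variance of each
#' component by the same spline procedure. The resulting model predicts time
#' for new observations by maximum likelihood (see [predict.ct_model()]).
#'
#' Only features with a nonzero loading in at least one of the first
#' `n_spc` components contribute to predictions; `sumabsv` controls how many
#' that is (smaller values give sparser, more interpretable predictors).
#'
#' @param data A [time_matrix()] of training observations.
#' @param sumabsv l1 budget per sparse component (default 2; `Inf` gives
#'   standard principal components).
#' @param n_spc Number of leading components used at prediction time
#'   (default 2); must not exceed `m`.
#' @param m Number of discretization time-points of the pattern matrix and
#'   number of extracted components (default 12).
#' @param n_knots Spline flexibility for mean curves (default 3).
#' @return An object of class `"ct_model"` with elements `loadings` (p x m
#'   matrix V), `spc_densities` (list of m `"time_density"`),
#'   `feature_ids`, `predictor_features`, `parameters`, `singular_values`
#'   and `variance_explained`.
#' @examples
#' sim <- default_benchmark(seed = 1)
#' model <- ct_train(sim$data, sumabsv = 3, n_spc = 2)
#' model$predictor_features
#' @export
ct_train <- function(data, sumabsv = 2, n_spc = 2, m = 12, n_knots = 3) {
  data <- as_time_matrix(data)
  n_spc <- as.integer(n_spc)
  m <- as.integer(m)
  if (n_spc < 1L || n_spc > m) {
    stop(sprintf("`n_spc` (%d) must be between 1 and m (%d)", n_spc, m))
  }
  densities <- .stage(fit_time_densities(data, n_knots), "time-density estimation")
  Zp <- .stage(build_pattern_matrix(densities, m), "pattern-matrix construction")
  dec <- .stage(pmd(Zp, sumabsv = sumabsv, n_components = m, orthogonal_u = TRUE),
                "penalized matrix decomposition")
  V <- dec$loadings
  scores <- .project_matrix(data$values, V, strict = FALSE)
  spc_data <- time_matrix(scores, data$times, period = 1,
                          feature_ids = colnames(V),
                          observation_ids = data$observation_ids)
  spc_densities <- .stage(fit_time_densities(spc_data, n_knots),
                          "component density estimation")
  nz <- rowSums(abs(V[, seq_len(n_spc), drop = FALSE]) > 0) > 0
  if (!any(nz)) stop("no feature has a nonzero loading in the first n_spc components")
  structure(
    list(loadings = V,
         spc_densities = spc_densities,
         feature_ids = data$feature_ids,
         predictor_features = data$feature_ids[nz],
         parameters = list(sumabsv = sumabsv, n_spc = n_spc, m = m,
                           n_knots = n_knots, period_units = data$period),
         singular_values = dec$d,
         variance_explained = variance_explained(dec, Zp),
         n_obs = nrow(data$values)),
    class = "ct_model"
  )
}

.stage <- function(expr, stage) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' @export
print.ct_model <- function(x, ...) {
  p <- x$parameters
  cat(sprintf("<ct_model> trained on %d observations x %d features\n",
              x$n_obs, length(x$feature_ids)))
  cat(sprintf("  sumabsv = %s, n_spc = %d, m = %d, n_knots = %d, period = %g\n",
              format(p$sumabsv), p$n_spc, p$m, p$n_knots, p$period_units))
  cat(sprintf("  predictor uses %d feature(s): %s\n",
              length(x$predictor_features),
              paste(utils::head(x$predictor_features, 8), collapse = ", ")))
  invisible(x)
}

# Available-case projection W %*% V. Missing entries contribute zero to the
# inner product and the loading mass of the missing features is renormalized
# out: score_ik = sum_j(obs) w_ij v_jk / sum_j(obs) v_jk^2. With complete
# data the denominator is ||v_k||_2^2 = 1 and this is the plain projection.
.project_matrix <- function(W, V, strict, predictor_idx = NULL,
                            observation_ids = rownames(W)) {
  if (anyNA(W)) {
    if (strict) {
      miss <- which(is.na(W[, predictor_idx, drop = FALSE]), arr.ind = TRUE)
      if (nrow(miss) > 0) {
        obs <- if (is.null(observation_ids)) as.character(miss[, 1]) else observation_ids[miss[, 1]]
        feat <- rownames(V)[predictor_idx][miss[, 2]]
        stop(sprintf(
          "test data cannot have missing measurements for the features used in the predictor: %s",
          paste(sprintf("observation '%s' feature '%s'", obs, feat), collapse = "; ")))
      }
    }
    obs_mask <- !is.na(W)
    W0 <- W
    W0[!obs_mask] <- 0
    num <- W0 %*% V
    den <- obs_mask %*% (V^2)
    scores <- ifelse(den > 0, num / den, 0)
  } else {
    scores <- W %*% V
  }
  dimnames(scores) <- list(observation_ids, colnames(V))
  scores
}

#' Project observations into sparse-component space
#'
#' Computes the component scores `w %*% V` for one or more observations.
#' Columns are aligned to the model's training features by name when the
#' input has column names (extra features are ignored); otherwise the column
#' count must match. Test observations must have no missing values among
#' the model's predictor features; missing values in other features are
#' handled by available-case renormalization.
#'
#' @param model A `"ct_model"`.
#' @param observations Numeric matrix (observations x features) or a single
#'   named/unnamed vector.
#' @return Numeric matrix of scores, observations x m.
#' @export
project <- function(model, observations) {
  stopifnot(inherits(model, "ct_model"))
  W <- .align_features(model, observations)
  pred_idx <- match(model$predictor_features, model$feature_ids)
  .project_matrix(W, model$loadings, strict = TRUE, predictor_idx = pred_idx)
}

.align_features <- function(model, observations) {
  if (is.null(dim(observations))) {
    observations <- matrix(observations, nrow = 1L,
                           dimnames = list(NULL, names(observations)))
  }
  W <- as.matrix(observations)
  p <- length(model$feature_ids)
  if (!is.null(colnames(W))) {
    missing_feat <- setdiff(model$feature_ids, colnames(W))
    if (length(missing_feat)) {
      stop("observations lack model feature(s): ",
           paste(utils::head(missing_feat, 5), collapse = ", "))
    }
    W <- W[, model$feature_ids, drop = FALSE]
  } else if (ncol(W) != p) {
    stop(sprintf("observations have %d features but the model was trained on %d (supply column names to align by id)",
                 ncol(W), p))
  }
  storage.mode(W) <- "double"
  W
}

#' Log-likelihood of a time given component scores
#'
#' Treating the leading components as independent Gaussians around their
#' periodic mean curves, returns
#' `sum_k [ -log(s_k sqrt(2 pi)) - (w_k - f_k(t))^2 / (2 s_k^2) ]`
#' over the first `n_spc` components. Vectorized over `t`, and periodic:
#' values at `t` and `t + 1` are identical.
#'
#' @param model A `"ct_model"`.
#' @param w_tilde Numeric vector of component scores (length at least
#'   `n_spc`).
#' @param t Numeric vector of candidate times (any real; reduced mod 1).
#' @param n_spc Number of components to use; defaults to the model's value.
#' @return Numeric vector of log-likelihood values, one per element of `t`.
#' @export
ct_log_likelihood <- function(model, w_tilde, t, n_spc = NULL) {
  stopifnot(inherits(model, "ct_model"))
  if (is.null(n_spc)) n_spc <- model$parameters$n_spc
  n_spc <- as.integer(n_spc)
  if (length(w_tilde) < n_spc) {
    stop(sprintf("`w_tilde` has %d entries but n_spc = %d", length(w_tilde), n_spc))
  }
  ll <- numeric(length(t))
  for (k in seq_len(n_spc)) {
    dk <- model$spc_densities[[k]]
    mu <- predict(dk$mean_curve, t)
    ll <- ll - 0.5 * log(2 * pi * dk$variance) -
      (w_tilde[k] - mu)^2 / (2 * dk$variance)
  }
  ll
}

# Maximize the log-likelihood over [0,1): evaluate on an even grid, then
# refine every cyclic local maximum with bounded golden-section/parabolic
# search. The likelihood is periodic and typically multimodal, so a single
# local search would be unsafe. Near-ties (within 1e-9 in log-likelihood)
# are broken to the smallest time.
.predict_from_scores <- function(model, w_tilde, n_spc = NULL, n_grid = 100L,
                                 keep_curve = FALSE) {
  if (is.null(n_spc)) n_spc <- model$parameters$n_spc
  grid <- (seq_len(n_grid) - 1L) / n_grid
  L <- ct_log_likelihood(model, w_tilde, grid, n_spc)
  left <- c(L[n_grid], L[-n_grid])
  right <- c(L[-1L], L[1L])
  local_max <- which(L >= left & L >= right)
  if (!length(local_max)) local_max <- which.max(L)
  h <- 1 / n_grid
  cand_t <- grid[local_max]
  cand_L <- L[local_max]
  for (i in seq_along(local_max)) {
    t0 <- grid[local_max[i]]
    opt <- stats::optimize(function(t) ct_log_likelihood(model, w_tilde, t %% 1, n_spc),
                           lower = t0 - h, upper = t0 + h,
                           maximum = TRUE, tol = 1e-7)
    if (opt$objective > cand_L[i]) {
      cand_t[i] <- .wrap01(opt$maximum)
      cand_L[i] <- opt$objective
    }
  }
  best <- max(cand_L)
  near <- which(cand_L >= best - 1e-9)
  pick <- near[which.min(cand_t[near])]
  structure(
    list(time_hat = cand_t[pick], log_likelihood = cand_L[pick],
         curve = if (keep_curve) data.frame(time = grid, log_likelihood = L)),
    class = "ct_prediction"
  )
}

#' @export
print.ct_prediction <- function(x, ...) {
  cat(sprintf("<ct_prediction> time_hat = %.4f (unit scale), log-likelihood = %.3f\n",
              x$time_hat, x$log_likelihood))
  invisible(x)
}

#' Predict the time of a single observation
#'
#' Projects the observation into component space and maximizes the Gaussian
#' log-likelihood over the circle.
#'
#' @param model A `"ct_model"`.
#' @param w Numeric vector (optionally named by feature) of one observation.
#' @param n_spc Override the number of components used.
#' @param keep_curve If `TRUE`, the returned object carries the sampled
#'   log-likelihood curve over the search grid.
#' @return A `"ct_prediction"`: list with `time_hat` in `[0, 1)`,
#'   `log_likelihood`, and optionally `curve`.
#' @export
ct_predict_one <- function(model, w, n_spc = NULL, keep_curve = FALSE) {
  scores <- project(model, w)
  .predict_from_scores(model, scores[1L, ], n_spc = n_spc, keep_curve = keep_curve)
}

#' Predict times for a matrix of observations
#'
#' @param object A `"ct_model"` from [ct_train()].
#' @param newdata Numeric matrix of observations x features (or a
#'   [time_matrix()]; its `times` are ignored). An empty matrix yields an
#'   empty result.
#' @param n_spc Override the number of components used at prediction time.
#' @param ... Unused.
#' @return A data.frame with one row per observation, in input order:
#'   `observation_id`, `time_hat` (unit scale), `time_hat_units`
#'   (multiplied by the training period, e.g. hours), `log_likelihood`.
#' @examples
#' sim <- default_benchmark(seed = 1)
#' model <- ct_train(sim$data, sumabsv = 3, n_spc = 2)
#' head(predict(model, sim$data$values))
#' @export
predict.ct_model <- function(object, newdata, n_spc = NULL, ...) {
  if (inherits(newdata, "time_matrix")) newdata <- newdata$values
  if (is.null(dim(newdata))) {
    newdata <- matrix(newdata, nrow = 1L, dimnames = list(NULL, names(newdata)))
  }
  n <- nrow(newdata)
  ids <- rownames(newdata)
  if (is.null(ids)) ids <- sprintf("obs%d", seq_len(n))
  if (n == 0L) {
    return(data.frame(observation_id = character(0), time_hat = numeric(0),
                      time_hat_units = numeric(0), log_likelihood = numeric(0),
                      stringsAsFactors = FALSE))
  }
  scores <- project(object, newdata)
  preds <- lapply(seq_len(n), function(i) {
    .predict_from_scores(object, scores[i, ], n_spc = n_spc)
  })
  data.frame(
    observation_id = ids,
    time_hat = vapply(preds, `[[`, numeric(1), "time_hat"),
    time_hat_units = vapply(preds, `[[`, numeric(1), "time_hat") *
      object$parameters$period_units,
    log_likelihood = vapply(preds, `[[`, numeric(1), "log_likelihood"),
    stringsAsFactors = FALSE
  )
}
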