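# ---- periodic smoothing spline on the unit circle -------------------------
#
# The time-dependent mean of a feature is a smooth periodic function of t on
# [0,1) with f(0) = f(1). We represent it in a truncated Fourier basis,
#   f(t) = a0 + sum_{h=1}^{H} a_h cos(2*pi*h*t) + b_h sin(2*pi*h*t),
# and fit by penalized least squares with the curvature penalty
# integral f''(t)^2 dt, which is diagonal in this basis:
# (2*pi*h)^4 * (a_h^2 + b_h^2) / 2. The smoothing parameter is chosen per
# curve by generalized cross-validation over a fixed lambda grid. The fit is
# exactly periodic by construction, so no seam constraint is needed.

.harmonic_basis <- function(t, H) {
  n <- length(t)
  B <- matrix(1, n, 2L * H + 1L)
  for (h in seq_len(H)) {
    B[, 2L * h] <- cos(2 * pi * h * t)
    B[, 2L * h + 1L] <- sin(2 * pi * h * t)
  }
  colnames(B) <- c("const", as.vector(rbind(paste0("cos", seq_len(H)),
                                            paste0("sin", seq_len(H)))))
  B
}

.curvature_penalty <- function(H) {
  c(0, rep((2 * pi * seq_len(H))^4 / 2, each = 2L))
}

.lambda_grid <- function() 10^seq(-12, 2, length.out = 29)

# Fit curves for all columns of Y at once (no missing values; shared times).
# Returns coefficient matrix q x p, plus per-column lambda/edf/rss.
.fit_periodic_batch <- function(times, Y, n_knots) {
  n <- length(times)
  n_distinct <- length(unique(times))
  H <- max(1L, min(as.integer(n_knots), (n_distinct - 1L) %/% 2L))
  B <- .harmonic_basis(times, H)
  pen <- .curvature_penalty(H)
  q <- ncol(B)
  BtB <- crossprod(B)
  BtY <- crossprod(B, Y)
  p <- ncol(Y)
  grid <- .lambda_grid()
  best_gcv <- rep(Inf, p)
  best_lambda <- rep(NA_real_, p)
  best_edf <- rep(NA_real_, p)
  best_coef <- matrix(0, q, p)
  best_rss <- rep(NA_real_, p)
  for (lambda in grid) {
    M <- BtB + diag(lambda * pen, q)
    A <- tryCatch(chol2inv(chol(M)), error = function(e) NULL)
    if (is.null(A)) next
    edf <- sum((B %*% A) * B)
    if (n - edf < 0.5) next
    coef <- A %*% BtY
    resid <- Y - B %*% coef
    rss <- colSums(resid^2)
    gcv <- n * rss / (n - edf)^2
    take <- gcv < best_gcv
    if (any(take)) {
      best_gcv[take] <- gcv[take]
      best_lambda[take] <- lambda
      best_edf[take] <- edf
      best_coef[, take] <- coef[, take]
      best_rss[take] <- rss[take]
    }
  }
  if (anyNA(best_lambda)) stop("penalized fit failed for all smoothing values")
  list(coef = best_coef, lambda = best_lambda, edf = best_edf,
       rss = best_rss, H = H, n = n)
}

.new_periodic_curve <- function(coef, H, n_knots, lambda, edf, n) {
  structure(
    list(coef = as.numeric(coef), harmonics = H, n_knots = as.integer(n_knots),
         lambda = lambda, edf = edf, n = n, period = 1),
    class = "periodic_curve"
  )
}

#' Fit a periodic smoothing spline to one feature
#'
#' Estimates the time-dependent mean of a measurement as a smooth periodic
#' function of the unit-scaled time, using a harmonic-basis smoothing spline
#' whose roughness penalty (integrated squared second derivative) is chosen
#' by generalized cross-validation. The fitted curve satisfies
#' `f(0) == f(1)` exactly.
#'
#' @param times Numeric vector of times in `[0, 1)`.
#' @param values Numeric vector of the same length; `NA` pairs are dropped.
#' @param n_knots Flexibility of the curve: the number of harmonic pairs in
#'   the basis (default 3). The effective number is capped so the fit stays
#'   identifiable when there are few distinct time-points.
#'
#' @return An object of class `"periodic_curve"`; evaluate it with
#'   [predict.periodic_curve()].
#' @examples
#' t <- (0:23) / 24
#' y <- cos(2 * pi * t) + rnorm(24, sd = 0.1)
#' curve <- fit_periodic_curve(t, y)
#' predict(curve, c(0, 0.25, 0.5))
#' @seealso [fit_time_densities()] for fitting all features of a matrix.
#' @export
fit_periodic_curve <- function(times, values, n_knots = 3) {
  if (length(times) != length(values)) {
    stop("`times` and `values` must have the same length")
  }
  if (!is.numeric(n_knots) || length(n_knots) != 1L || n_knots < 2) {
    stop("`n_knots` must be a single integer >= 2")
  }
  keep <- !is.na(times) & !is.na(values)
  if (!any(keep)) stop("all values are missing; nothing to fit")
  times <- times[keep]
  values <- values[keep]
  if (any(times < 0 | times >= 1)) stop("`times` must lie in [0, 1)")
  if (length(unique(times)) < 3L) {
    stop("need at least 3 distinct time values after dropping missing entries")
  }
  fit <- .fit_periodic_batch(times, matrix(values, ncol = 1L), n_knots)
  .new_periodic_curve(fit$coef[, 1L], fit$H, n_knots, fit$lambda[1L],
                      fit$edf[1L], fit$n)
}

#' Evaluate a fitted periodic curve
#'
#' @param object A `"periodic_curve"` from [fit_periodic_curve()].
#' @param t Numeric vector of times; reduced modulo 1 before evaluation, so
#'   the curve is periodic for any real input.
#' @param ... Unused.
#' @return Numeric vector of fitted mean values.
#' @export
predict.periodic_curve <- function(object, t, ...) {
  B <- .harmonic_basis(t %% 1, object$harmonics)
  drop(B %*% object$coef)
}

#' @export
print.periodic_curve <- function(x, ...) {
  cat(sprintf("<periodic_curve> %d harmonic pairs, edf %.2f, lambda %.3g, n = %d\n",
              x$harmonics, x$edf, x$lambda, x$n))
  invisible(x)
}

#' Estimate the variance about a fitted periodic mean curve
#'
#' Returns the mean squared residual `RSS / n` of the observations about the
#' curve, the constant (time-independent) variance of the feature's Gaussian
#' conditional density. A small positive floor is applied so that noiseless
#' features never yield a zero variance, which would break the
#' signal-to-noise scaling of the pattern matrix and produce infinite
#' likelihoods.
#'
#' @param curve A `"periodic_curve"`.
#' @param times,values Numeric vectors; `NA` pairs are dropped.
#' @return A single positive number.
#' @examples
#' t <- (0:23) / 24
#' y <- cos(2 * pi * t) + rnorm(24, sd = 0.5)
#' curve <- fit_periodic_curve(t, y)
#' estimate_variance(curve, t, y)
#' @export
estimate_variance <- function(curve, times, values) {
  stopifnot(inherits(curve, "periodic_curve"))
  if (length(times) != length(values)) {
    stop("`times` and `values` must have the same length")
  }
  keep <- !is.na(times) & !is.na(values)
  if (!any(keep)) stop("no non-missing (time, value) pairs to estimate variance from")
  times <- times[keep]
  values <- values[keep]
  resid <- values - predict(curve, times)
  v <- mean(resid^2)
  max(v, .variance_floor(values))
}

.variance_floor <- function(values) {
  rng <- diff(range(values, finite = TRUE))
  if (is.finite(rng) && rng > 0) 1e-8 * rng^2 else 1e-12
}

#' Fit time-dependent densities for every feature of a matrix
#'
#' For each feature (column), fits the periodic smoothing spline of
#' [fit_periodic_curve()] to obtain the time-dependent mean, and estimates
#' the constant variance about that mean from the residuals
#' ([estimate_variance()]). Together these define the Gaussian conditional
#' density of the feature given time. Missing entries are dropped per
#' feature; features sharing a complete design are fitted in one batched
#' pass.
#'
#' @param data A [time_matrix()].
#' @param n_knots Number of harmonic pairs in the spline basis (default 3).
#' @return A list of `"time_density"` objects, one per feature in column
#'   order, each with elements `mean_curve`, `variance`, `n_used` and
#'   `feature_id`.
#' @examples
#' sim <- default_benchmark(seed = 1)
#' dens <- fit_time_densities(sim$data)
#' dens[[1]]$variance
#' @export
fit_time_densities <- function(data, n_knots = 3) {
  data <- as_time_matrix(data)
  p <- ncol(data$values)
  out <- vector("list", p)
  complete <- !apply(data$values, 2L, anyNA)
  if (any(complete)) {
    Y <- data$values[, complete, drop = FALSE]
    if (length(unique(data$times)) < 3L) {
      stop("need at least 3 distinct time values to fit time densities")
    }
    fit <- .fit_periodic_batch(data$times, Y, n_knots)
    fitted <- .harmonic_basis(data$times, fit$H) %*% fit$coef
    idx <- which(complete)
    for (i in seq_along(idx)) {
      j <- idx[i]
      v <- fit$rss[i] / fit$n
      v <- max(v, .variance_floor(Y[, i]))
      out[[j]] <- structure(
        list(mean_curve = .new_periodic_curve(fit$coef[, i], fit$H, n_knots,
                                              fit$lambda[i], fit$edf[i], fit$n),
             variance = v, n_used = fit$n, feature_id = data$feature_ids[j]),
        class = "time_density"
      )
    }
  }
  for (j in which(!complete)) {
    id <- data$feature_ids[j]
    out[[j]] <- tryCatch({
      curve <- fit_periodic_curve(data$times, data$values[, j], n_knots)
      structure(
        list(mean_curve = curve,
             variance = estimate_variance(curve, data$times, data$values[, j]),
             n_used = curve$n, feature_id = id),
        class = "time_density"
      )
    }, error = function(e) {
      stop(sprintf("feature '%s': %s", id, conditionMessage(e)), call. = FALSE)
    })
  }
  names(out) <- data$feature_ids
  out
}

#' @export
print.time_density <- function(x, ...) {
  cat(sprintf("<time_density> feature '%s': variance %.4g, n_used %d\n",
              x$feature_id, x$variance, x$n_used))
  invisible(x)
}
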