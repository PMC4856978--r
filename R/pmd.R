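# ---- pattern matrix and penalized matrix decomposition --------------------

#' Build the discretized, noise-scaled pattern matrix
#'
#' Evaluates each feature's fitted mean curve at `m` evenly spaced
#' time-points `tau_i = (i-1)/m`, centers each feature over those
#' time-points, and divides by the feature's residual standard deviation, so
#' every entry is expressed in signal-to-noise units:
#' `z_ij = (f_j(tau_i) - mean_i f_j(tau_i)) / s_j`.
#' The resulting m x p matrix is the object whose sparse principal
#' components are extracted by [pmd()]; `m` is also the maximum number of
#' components available for prediction.
#'
#' @param densities List of `"time_density"` objects from
#'   [fit_time_densities()].
#' @param m Number of time-points (rows), at least 2; default 12.
#' @return An object of class `"pattern_matrix"`: list with `z` (m x p),
#'   `timepoints` and `feature_ids`.
#' @examples
#' sim <- default_benchmark(seed = 1)
#' dens <- fit_time_densities(sim$data)
#' Z <- build_pattern_matrix(dens, m = 12)
#' dim(Z$z)
#' @export
build_pattern_matrix <- function(densities, m = 12) {
  if (!length(densities)) stop("`densities` is empty")
  if (!is.numeric(m) || length(m) != 1L || m < 2) stop("`m` must be an integer >= 2")
  m <- as.integer(m)
  vars <- vapply(densities, function(d) d$variance, numeric(1))
  ids <- vapply(densities, function(d) d$feature_id, character(1))
  if (any(!is.finite(vars) | vars <= 0)) {
    bad <- ids[!is.finite(vars) | vars <= 0]
    stop("non-positive variance for feature(s): ", paste(bad, collapse = ", "))
  }
  tau <- (seq_len(m) - 1L) / m
  Fmat <- vapply(densities, function(d) predict(d$mean_curve, tau), numeric(m))
  Fmat <- matrix(Fmat, nrow = m)
  Z <- sweep(Fmat, 2L, colMeans(Fmat))
  Z <- sweep(Z, 2L, sqrt(vars), "/")
  colnames(Z) <- ids
  structure(list(z = Z, timepoints = tau, feature_ids = unname(ids)),
            class = "pattern_matrix")
}

#' @export
print.pattern_matrix <- function(x, ...) {
  cat(sprintf("<pattern_matrix> %d time-points x %d features\n",
              nrow(x$z), ncol(x$z)))
  invisible(x)
}

.as_z_matrix <- function(Z) {
  if (inherits(Z, "pattern_matrix")) Z$z else as.matrix(Z)
}

# soft-threshold operator
.soft <- function(a, delta) sign(a) * pmax(abs(a) - delta, 0)

# Return the unit-l2 vector proportional to S(a, delta) whose l1 norm is at
# most `c`, with delta = 0 whenever the unthresholded vector already
# complies; delta found by bisection (<= 50 iterations, tolerance 1e-8 on
# the l1 norm).
.l1_unit <- function(a, c) {
  na <- sqrt(sum(a^2))
  if (na == 0) return(a)
  v <- a / na
  if (is.infinite(c) || sum(abs(v)) <= c + 1e-6) return(v)
  lo <- 0
  hi <- max(abs(a))
  for (iter in seq_len(50L)) {
    mid <- (lo + hi) / 2
    s <- .soft(a, mid)
    v_mid <- s / sqrt(sum(s^2))
    l1 <- sum(abs(v_mid))
    if (abs(l1 - c) <= 1e-8) return(v_mid)
    if (l1 > c) lo <- mid else hi <- mid
  }
  s <- .soft(a, hi)
  s / sqrt(sum(s^2))
}

# deterministic sign convention: largest-|loading| entry positive
# (ties broken to the lowest feature index by which.max)
.fix_sign <- function(u, v) {
  i <- which.max(abs(v))
  if (v[i] < 0) list(u = -u, v = -v) else list(u = u, v = v)
}

#' Rank-1 penalized matrix decomposition
#'
#' Approximately maximizes `t(u) %*% Z %*% v` subject to `||u||_2 <= 1`,
#' `||v||_2 <= 1` and `||v||_1 <= sumabsv`, by alternating updates:
#' `u <- Zv / ||Zv||_2` and `v <- S(t(Z)u, delta) / ||.||_2`, where `S` is
#' entrywise soft-thresholding and `delta` is the smallest value meeting the
#' l1 budget (bisection). `v` is initialized at the leading right singular
#' vector of `Z`; iteration stops when the objective changes by less than
#' 1e-7 or after 100 iterations. The l1 budget is what makes the component
#' sparse: at `sumabsv = 1` exactly one loading is nonzero, at
#' `sumabsv = sqrt(p)` the constraint is inactive and the component equals
#' the leading singular vector. `sumabsv = Inf` is accepted as a sentinel
#' for the unconstrained case.
#'
#' @param Z Numeric matrix (or a `"pattern_matrix"`), m x p.
#' @param sumabsv l1 budget for the loadings, in `[1, sqrt(p)]`, or `Inf`.
#' @return An object of class `"sparse_component"`: list with `loadings`
#'   (unit-l2 vector of length p, sign fixed so the largest-magnitude
#'   loading is positive), `left_vector` (length m), `singular_value`
#'   (`>= 0`), `n_nonzero` and `converged`.
#' @export
pmd_rank1 <- function(Z, sumabsv) {
  Z <- .as_z_matrix(Z)
  if (!all(is.finite(Z))) stop("`Z` must be finite")
  p <- ncol(Z)
  m <- nrow(Z)
  if (!is.infinite(sumabsv) &&
      (sumabsv < 1 - 1e-9 || sumabsv > sqrt(p) + 1e-9)) {
    stop(sprintf(
      "`sumabsv` must lie in [1, sqrt(p)] = [1, %.4f] for p = %d features (or Inf for no l1 constraint)",
      sqrt(p), p))
  }
  if (max(abs(Z)) == 0) {
    v <- c(1, rep(0, p - 1L))
    return(structure(list(loadings = v, left_vector = rep(0, m),
                          singular_value = 0, n_nonzero = 1L, converged = TRUE),
                     class = "sparse_component"))
  }
  v <- svd(Z, nu = 0L, nv = 1L)$v[, 1L]
  d_old <- -Inf
  converged <- FALSE
  u <- rep(0, m)
  for (iter in seq_len(100L)) {
    zv <- drop(Z %*% v)
    nz <- sqrt(sum(zv^2))
    if (nz == 0) break
    u <- zv / nz
    v <- .l1_unit(drop(crossprod(Z, u)), sumabsv)
    d <- sum(u * (Z %*% v))
    if (abs(d - d_old) < 1e-7) {
      converged <- TRUE
      break
    }
    d_old <- d
  }
  if (!converged) {
    warning("rank-1 PMD did not converge within 100 iterations; returning last iterate")
  }
  # final polish of u so that d = ||Zv||_2 >= 0
  zv <- drop(Z %*% v)
  nz <- sqrt(sum(zv^2))
  if (nz > 0) u <- zv / nz
  d <- sum(u * (Z %*% v))
  s <- .fix_sign(u, v)
  structure(
    list(loadings = s$v, left_vector = s$u, singular_value = d,
         n_nonzero = sum(s$v != 0), converged = converged),
    class = "sparse_component"
  )
}

#' Penalized matrix decomposition into sparse principal components
#'
#' Extracts `n_components` rank-1 factors sequentially with [pmd_rank1()].
#' With `orthogonal_u = TRUE` (the default), before extracting factor k+1
#' the matrix is projected onto the orthogonal complement of the left
#' vectors `u_1..u_k`, which keeps the left vectors mutually orthogonal and
#' discourages the sparse components from being highly correlated; otherwise
#' classical rank-1 deflation (`Z - d u v'`) is used.
#'
#' @param Z Numeric matrix or `"pattern_matrix"`, m x p.
#' @param sumabsv l1 budget per component (see [pmd_rank1()]); default 2.
#' @param n_components Number of factors, at most m; default m.
#' @param orthogonal_u Keep left vectors orthogonal (default `TRUE`).
#' @return An object of class `"pmd_decomposition"`: list with `components`
#'   (list of `"sparse_component"`), `loadings` (p x n_components matrix V),
#'   `d` (objective values), `sumabsv`, `orthogonal_u` and `frobenius2`
#'   (`sum(Z^2)`).
#' @examples
#' Z <- matrix(rnorm(12 * 50), 12, 50)
#' dec <- pmd(Z, sumabsv = 3, n_components = 2)
#' dec$components[[1]]$n_nonzero
#' @export
pmd <- function(Z, sumabsv = 2, n_components = NULL, orthogonal_u = TRUE) {
  Z <- .as_z_matrix(Z)
  m <- nrow(Z)
  p <- ncol(Z)
  if (is.null(n_components)) n_components <- m
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > m) {
    stop(sprintf("`n_components` must be between 1 and m = %d (the number of rows of Z)", m))
  }
  comps <- vector("list", n_components)
  U <- NULL
  R <- Z
  for (k in seq_len(n_components)) {
    if (max(abs(R)) < 1e-12) {
      comps[[k]] <- structure(
        list(loadings = c(1, rep(0, p - 1L)), left_vector = rep(0, m),
             singular_value = 0, n_nonzero = 1L, converged = TRUE),
        class = "sparse_component")
    } else {
      comps[[k]] <- pmd_rank1(R, sumabsv)
    }
    u <- comps[[k]]$left_vector
    if (orthogonal_u) {
      if (sqrt(sum(u^2)) > 0) {
        U <- cbind(U, u)
        R <- Z - U %*% crossprod(U, Z)
      }
    } else {
      R <- R - comps[[k]]$singular_value * tcrossprod(u, comps[[k]]$loadings)
    }
  }
  V <- vapply(comps, function(cp) cp$loadings, numeric(p))
  V <- matrix(V, nrow = p,
              dimnames = list(colnames(Z), paste0("SPC", seq_len(n_components))))
  structure(
    list(components = comps, loadings = V,
         d = vapply(comps, function(cp) cp$singular_value, numeric(1)),
         sumabsv = sumabsv, orthogonal_u = orthogonal_u,
         frobenius2 = sum(Z^2)),
    class = "pmd_decomposition"
  )
}

#' @export
print.pmd_decomposition <- function(x, ...) {
  cat(sprintf("<pmd_decomposition> %d components, sumabsv = %s\n",
              length(x$components), format(x$sumabsv)))
  nz <- vapply(x$components, function(cp) cp$n_nonzero, integer(1))
  cat("  nonzero loadings per component:", paste(nz, collapse = ", "), "\n")
  invisible(x)
}

#' Fraction of variance explained by each component
#'
#' Per-component fraction `d_k^2 / ||Z||_F^2`, where `d_k` is the objective
#' value attained on the (sequentially deflated) matrix. In the unpenalized
#' case these equal the squared singular values over their sum.
#'
#' @param decomposition A `"pmd_decomposition"` of `Z`.
#' @param Z The matrix (or `"pattern_matrix"`) that was decomposed.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
variance_explained <- function(decomposition, Z) {
  stopifnot(inherits(decomposition, "pmd_decomposition"))
  Z <- .as_z_matrix(Z)
  tot <- sum(Z^2)
  if (tot == 0) return(rep(0, length(decomposition$d)))
  decomposition$d^2 / tot
}
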