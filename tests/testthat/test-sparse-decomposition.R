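test_that("pattern matrix discretizes, centers and noise-scales mean curves", {
  dens <- list(
    make_density(make_cos_curve(1, 0), variance = 1, feature_id = "cos"),
    make_density(make_cos_curve(1, 0), variance = 4, feature_id = "cos_noisy"),
    make_density(make_cos_curve(0, 0, intercept = 7), variance = 2, feature_id = "flat")
  )
  Z <- build_pattern_matrix(dens, m = 4)
  expect_equal(Z$timepoints, c(0, 0.25, 0.5, 0.75))
  expect_equal(Z$z[, 1], c(1, 0, -1, 0), tolerance = 1e-12)
  # doubling the residual sd halves the column
  expect_equal(Z$z[, 2], c(1, 0, -1, 0) / 2, tolerance = 1e-12)
  # constant mean curve gives an all-zero column
  expect_equal(Z$z[, 3], rep(0, 4))
  # every column has mean zero
  expect_true(all(abs(colMeans(Z$z)) < 1e-10))
})

test_that("pattern matrix rejects bad inputs", {
  dens <- list(make_density(make_cos_curve(), variance = 0, feature_id = "zv"))
  expect_error(build_pattern_matrix(dens, m = 4), "zv")
  expect_error(build_pattern_matrix(list(), m = 4), "empty")
  good <- list(make_density(make_cos_curve(), variance = 1))
  expect_error(build_pattern_matrix(good, m = 1), "m")
})

test_that("sumabsv = 1 forces a single unit loading at the dominant column", {
  Z <- matrix(0, 4, 6)
  Z[1, 3] <- 5
  Z[2, 5] <- 1
  cp <- pmd_rank1(Z, sumabsv = 1)
  expect_identical(cp$n_nonzero, 1L)
  expect_equal(which(cp$loadings != 0), 3L)
  expect_equal(abs(cp$loadings[3]), 1)
  expect_gte(cp$singular_value, 0)
})

test_that("unconstrained component equals the leading singular vector", {
  set.seed(20)
  for (rep in 1:3) {
    Z <- matrix(rnorm(12 * 50), 12, 50)
    cp <- pmd_rank1(Z, sumabsv = sqrt(50))
    sv <- svd(Z, nu = 1, nv = 1)
    v1 <- sv$v[, 1]
    if (v1[which.max(abs(v1))] < 0) v1 <- -v1
    expect_lt(max(abs(cp$loadings - v1)), 1e-4)
    expect_equal(cp$singular_value, sv$d[1], tolerance = 1e-6)
  }
})

test_that("a planted sparse factor's support is recovered", {
  set.seed(33)
  p <- 40
  v <- rep(0, p)
  v[c(4, 17, 29)] <- c(0.8, -0.5, 0.33)
  v <- v / sqrt(sum(v^2))
  u <- rnorm(10)
  u <- u / sqrt(sum(u^2))
  Z <- 6 * tcrossprod(u, v)
  cp <- pmd_rank1(Z, sumabsv = sum(abs(v)) + 0.05)
  expect_setequal(which(cp$loadings != 0), c(4, 17, 29))
})

test_that("sumabsv outside its valid range is explained", {
  Z <- matrix(rnorm(20), 4, 5)
  expect_error(pmd_rank1(Z, 0.5), "\\[1, sqrt\\(p\\)\\]")
  expect_error(pmd_rank1(Z, 10), "\\[1, sqrt\\(p\\)\\]")
  expect_silent(pmd_rank1(Z, Inf))
})

test_that("soft-threshold bisection honors the l1 budget", {
  set.seed(8)
  for (rep in 1:20) {
    p <- sample(5:80, 1)
    a <- rnorm(p) * 10^runif(1, -2, 2)
    c <- runif(1, 1, sqrt(p))
    v <- circatime:::.l1_unit(a, c)
    expect_equal(sqrt(sum(v^2)), 1, tolerance = 1e-8)
    expect_lte(sum(abs(v)), c + 1e-6)
    v0 <- a / sqrt(sum(a^2))
    if (sum(abs(v0)) <= c + 1e-6) expect_identical(v, v0)
  }
})

test_that("component sparsity grows monotonically with sumabsv", {
  set.seed(5)
  Z <- matrix(rnorm(12 * 60), 12, 60)
  nz <- vapply(c(1, 1.5, 2, 3, 4, 6, sqrt(60)),
               function(c) pmd_rank1(Z, c)$n_nonzero, integer(1))
  expect_true(all(diff(nz) >= 0))
})

test_that("orthogonal patterns on disjoint feature blocks separate into components", {
  tau <- (0:11) / 12
  Z <- matrix(0, 12, 20)
  Z[, 1:10] <- 3 * cos(2 * pi * tau)
  Z[, 11:20] <- 2 * sin(2 * pi * tau)
  dec <- pmd(Z, sumabsv = sqrt(10), n_components = 2)
  # the l1 budget is exactly at the unconstrained solution, so no entry is
  # hard-thresholded away; judge support at numerical-noise level
  s1 <- which(abs(dec$loadings[, 1]) > 1e-8)
  s2 <- which(abs(dec$loadings[, 2]) > 1e-8)
  expect_length(intersect(s1, s2), 0)
  expect_true(setequal(union(s1, s2), 1:20))
  u1 <- dec$components[[1]]$left_vector
  u2 <- dec$components[[2]]$left_vector
  expect_lt(abs(sum(u1 * u2)), 1e-6)
})

test_that("full unpenalized decomposition reconstructs the matrix like the SVD", {
  set.seed(44)
  Z <- matrix(rnorm(12 * 30), 12, 30)
  dec <- pmd(Z, sumabsv = sqrt(30), n_components = 12)
  recon <- Reduce(`+`, lapply(1:12, function(k) {
    dec$d[k] * tcrossprod(dec$components[[k]]$left_vector, dec$loadings[, k])
  }))
  expect_lt(sqrt(sum((recon - Z)^2)), 1e-3)
  # left vectors pairwise orthogonal
  U <- sapply(dec$components, `[[`, "left_vector")
  G <- crossprod(U)
  expect_lt(max(abs(G - diag(12))), 1e-6)
})

test_that("variance explained matches the SVD spectrum when unpenalized", {
  set.seed(50)
  Z <- matrix(rnorm(12 * 50), 12, 50)
  dec <- pmd(Z, sumabsv = sqrt(50), n_components = 12)
  sv <- svd(Z)
  expect_lt(max(abs(variance_explained(dec, Z) - sv$d^2 / sum(sv$d^2))), 1e-4)

  # rank-1 matrix: all variance in the first component
  Z1 <- tcrossprod(rnorm(12), rnorm(50))
  dec1 <- pmd(Z1, sumabsv = sqrt(50), n_components = 3)
  ve <- variance_explained(dec1, Z1)
  expect_equal(ve[1], 1, tolerance = 1e-8)
  expect_true(all(abs(ve[-1]) < 1e-8))

  # zero matrix: all zero
  dec0 <- pmd(matrix(0, 4, 6), sumabsv = 2, n_components = 2)
  expect_equal(variance_explained(dec0, matrix(0, 4, 6)), c(0, 0))
})

test_that("decomposition is deterministic and sign-stable", {
  set.seed(60)
  Z <- matrix(rnorm(12 * 40), 12, 40)
  d1 <- pmd(Z, sumabsv = 2, n_components = 4)
  d2 <- pmd(Z, sumabsv = 2, n_components = 4)
  expect_identical(d1, d2)
  # largest-magnitude loading is positive in every component
  for (cp in d1$components) {
    expect_gt(cp$loadings[which.max(abs(cp$loadings))], 0)
  }
})

test_that("flipping a feature's sign flips only that loading's sign", {
  set.seed(61)
  Z <- matrix(rnorm(12 * 30), 12, 30)
  d1 <- pmd(Z, sumabsv = 3, n_components = 2)
  Zf <- Z
  Zf[, 7] <- -Zf[, 7]
  d2 <- pmd(Zf, sumabsv = 3, n_components = 2)
  expect_equal(abs(d2$loadings), abs(d1$loadings), tolerance = 1e-8)
  expect_equal(d2$d, d1$d, tolerance = 1e-8)
})
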