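test_that("sumabsv = 1 with two sinusoidal features yields a two-feature predictor", {
  sim <- make_sin_data(n_signal = 2, n_noise = 48, noise_sd = 0.1,
                       phases = c(0, 0.25), amplitudes = 2, seed = 2)
  model <- ct_train(sim$data, sumabsv = 1, n_spc = 2)
  expect_setequal(model$predictor_features, sim$truth$signal_features)
  expect_length(model$predictor_features, 2)
})

test_that("training is deterministic and validates n_spc", {
  sim <- make_sin_data(seed = 3)
  m1 <- ct_train(sim$data, sumabsv = 2, n_spc = 2)
  m2 <- ct_train(sim$data, sumabsv = 2, n_spc = 2)
  expect_identical(m1, m2)
  expect_error(ct_train(sim$data, sumabsv = 2, n_spc = 13, m = 12), "n_spc")
})

test_that("projection is linear and consistent with the loadings", {
  sim <- make_sin_data(seed = 4)
  model <- ct_train(sim$data, sumabsv = 2, n_spc = 2)
  p <- length(model$feature_ids)
  expect_equal(drop(project(model, rep(0, p))), setNames(rep(0, 12), colnames(model$loadings)))
  w <- rep(0, p)
  j <- match(model$predictor_features[1], model$feature_ids)
  w[j] <- 1
  expect_equal(drop(project(model, w)), model$loadings[j, ], tolerance = 1e-12)
})

test_that("test observations may not miss predictor features", {
  sim <- make_sin_data(seed = 5)
  model <- ct_train(sim$data, sumabsv = 1, n_spc = 2)
  W <- sim$data$values[1:2, ]
  W[2, model$predictor_features[1]] <- NA
  err <- tryCatch(project(model, W), error = conditionMessage)
  expect_match(err, "cannot have missing measurements")
  expect_match(err, model$predictor_features[1], fixed = TRUE)
  expect_match(err, rownames(W)[2], fixed = TRUE)
  # missing values in non-predictor features are tolerated
  W2 <- sim$data$values[1:2, ]
  np <- setdiff(model$feature_ids, model$predictor_features)[1]
  W2[1, np] <- NA
  expect_silent(project(model, W2))
})

test_that("log-likelihood has the Gaussian form and is additive over components", {
  d1 <- make_density(make_cos_curve(1, 0), variance = 1 / (2 * pi))
  d2 <- make_density(make_cos_curve(1, 0.25), variance = 0.5)
  model <- make_toy_model(list(d1, d2), loadings = diag(2), n_spc = 2)
  t0 <- 0.3
  w1 <- predict(d1$mean_curve, t0)
  # density value 1 at the mean when variance = 1/(2*pi)
  expect_equal(ct_log_likelihood(model, c(w1, 0), t0, n_spc = 1), 0)
  # moving off the mean by delta costs delta^2 / (2 s^2)
  delta <- 0.7
  expect_equal(ct_log_likelihood(model, c(w1 + delta, 0), t0, n_spc = 1),
               -delta^2 * pi)
  # additivity across components
  ll1 <- ct_log_likelihood(model, c(w1, 0.2), t0, n_spc = 1)
  m2 <- make_toy_model(list(d2, d1), loadings = diag(2), n_spc = 1)
  ll2 <- ct_log_likelihood(m2, c(0.2, 0), t0, n_spc = 1)
  expect_equal(ct_log_likelihood(model, c(w1, 0.2), t0, n_spc = 2), ll1 + ll2)
})

test_that("the likelihood is periodic in t", {
  sim <- make_sin_data(seed = 6)
  model <- ct_train(sim$data, sumabsv = 2, n_spc = 2)
  w <- project(model, sim$data$values[5, , drop = FALSE])[1, ]
  t <- seq(0, 0.99, length.out = 37)
  expect_equal(ct_log_likelihood(model, w, t),
               ct_log_likelihood(model, w, t + 1), tolerance = 1e-8)
  expect_equal(ct_log_likelihood(model, w, t),
               ct_log_likelihood(model, w, t - 1), tolerance = 1e-8)
})

test_that("a noiseless observation on the training curves is predicted at its time", {
  sim <- make_sin_data(n_signal = 10, n_noise = 90, noise_sd = 0.2,
                       phases = "spread", amplitudes = seq(1, 3, length.out = 10),
                       seed = 7)
  model <- ct_train(sim$data, sumabsv = 3, n_spc = 2)
  t0 <- 0.3
  w <- rep(0, length(model$feature_ids))
  names(w) <- model$feature_ids
  sig <- sim$truth$signal_features
  w[sig] <- sim$truth$amplitude * cos(2 * pi * (t0 - sim$truth$phase))
  pred <- ct_predict_one(model, w, keep_curve = TRUE)
  expect_lt(abs(circular_error(t0, pred$time_hat)), 0.01)
  # achieved log-likelihood at least the best sampled grid value
  expect_gte(pred$log_likelihood, max(pred$curve$log_likelihood) - 1e-9)
})

test_that("symmetric likelihoods break ties toward the smaller time", {
  d <- make_density(make_cos_curve(1, 0), variance = 0.2)
  model <- make_toy_model(list(d), loadings = matrix(1, 1, 1), n_spc = 1)
  # score 0 sits between peak and trough: maxima at t = 0.25 and 0.75
  pred <- circatime:::.predict_from_scores(model, 0, n_spc = 1)
  expect_equal(pred$time_hat, 0.25, tolerance = 1e-4)
})

test_that("grid-plus-refinement matches a dense brute-force argmax", {
  sim <- make_sin_data(n_signal = 6, n_noise = 44, noise_sd = 0.4,
                       phases = "uniform", amplitudes = c(1, 2), seed = 8)
  model <- ct_train(sim$data, sumabsv = 2, n_spc = 2)
  grid <- (0:9999) / 10000
  set.seed(9)
  for (i in sample(nrow(sim$data$values), 20)) {
    w <- project(model, sim$data$values[i, , drop = FALSE])[1, ]
    bf <- grid[which.max(ct_log_likelihood(model, w, grid))]
    pred <- circatime:::.predict_from_scores(model, w)
    expect_lt(abs(circular_error(bf, pred$time_hat)), 2e-4)
  }
})

test_that("only predictor features influence predictions", {
  sim <- make_sin_data(seed = 10)
  model <- ct_train(sim$data, sumabsv = 1, n_spc = 2)
  W <- sim$data$values[1:5, ]
  W0 <- W
  W0[, setdiff(model$feature_ids, model$predictor_features)] <- 0
  expect_identical(predict(model, W), predict(model, W0))
})

test_that("batch prediction preserves order, handles empty input and permutes", {
  sim <- make_sin_data(seed = 11)
  model <- ct_train(sim$data, sumabsv = 2, n_spc = 2)
  W <- sim$data$values[1:6, ]
  empty <- predict(model, W[0, , drop = FALSE])
  expect_identical(nrow(empty), 0L)
  one <- predict(model, W[3, , drop = FALSE])
  batch <- predict(model, W)
  expect_equal(one$time_hat, batch$time_hat[3])
  perm <- c(4, 1, 6, 2, 5, 3)
  expect_equal(predict(model, W[perm, ])$time_hat, batch$time_hat[perm])
})

test_that("more components do not hurt accuracy on the synthetic benchmark", {
  sim <- default_benchmark(seed = 21)
  cv <- leave_one_group_out_cv(sim$data, sim$groups,
                               param_grid = data.frame(sumabsv = 2, n_spc = c(1, 2)))
  expect_lte(cv[[2]]$overall_mae, cv[[1]]$overall_mae)
  expect_lt(cv[[2]]$overall_mae, 0.042)
})
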