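# Shared fixture builders: everything is generated in code at test time.

# A periodic_curve evaluating to A * cos(2*pi*(t - phase)) exactly.
make_cos_curve <- function(amplitude = 1, phase = 0, intercept = 0) {
  coef <- c(intercept,
            amplitude * cos(2 * pi * phase),
            amplitude * sin(2 * pi * phase))
  circatime:::.new_periodic_curve(coef, H = 1L, n_knots = 3L, lambda = 0,
                                  edf = 3, n = 0L)
}

make_density <- function(curve, variance = 1, feature_id = "f", n_used = 0L) {
  structure(list(mean_curve = curve, variance = variance, n_used = n_used,
                 feature_id = feature_id),
            class = "time_density")
}

# Minimal hand-built ct_model with given SPC densities and loadings.
make_toy_model <- function(spc_densities, loadings, n_spc = length(spc_densities)) {
  p <- nrow(loadings)
  feature_ids <- sprintf("f%d", seq_len(p))
  rownames(loadings) <- feature_ids
  colnames(loadings) <- paste0("SPC", seq_len(ncol(loadings)))
  nz <- rowSums(abs(loadings[, seq_len(n_spc), drop = FALSE]) > 0) > 0
  structure(
    list(loadings = loadings, spc_densities = spc_densities,
         feature_ids = feature_ids, predictor_features = feature_ids[nz],
         parameters = list(sumabsv = Inf, n_spc = n_spc,
                           m = ncol(loadings), n_knots = 3, period_units = 1),
         singular_values = rep(NA_real_, ncol(loadings)),
         variance_explained = rep(NA_real_, ncol(loadings)),
         n_obs = 0L),
    class = "ct_model"
  )
}

# Small two-group sinusoidal time course with named features.
make_sin_data <- function(n_signal = 2, n_noise = 48, noise_sd = 0.1,
                          phases = c(0, 0.25), amplitudes = 2, seed = 1,
                          n_groups = 2) {
  simulate_oscillatory(sim_config(
    n_signal_features = n_signal, n_noise_features = n_noise,
    n_timepoints = 12, n_replicates = 2, n_groups = n_groups,
    amplitudes = amplitudes, phases = phases, noise_sd = noise_sd,
    seed = seed))
}
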