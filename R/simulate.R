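# ---- synthetic oscillatory datasets with known ground truth ---------------

#' Configuration for the oscillatory-data simulator
#'
#' Describes a multi-group time-course design: `n_groups` groups (stand-ins
#' for organs or batches), each sampled at `n_timepoints` evenly spaced
#' times per cycle with `n_replicates` cycles/replicates. Signal features
#' oscillate with per-feature amplitude and phase on top of Gaussian noise;
#' noise features are pure Gaussian noise. Group baseline offsets (drawn
#' per group and feature with standard deviation `group_shift_sd`) emulate
#' residual organ effects; the default of 0 reflects input data that have
#' already been batch-corrected.
#'
#' @param n_signal_features,n_noise_features Feature counts (defaults 20
#'   and 480).
#' @param n_timepoints Time-points per cycle (default 12, i.e. every 2 h on
#'   a 24 h clock).
#' @param n_replicates Replicates per (group, time-point) (default 2).
#' @param n_groups Number of groups (default 3).
#' @param amplitudes Numeric vector recycled over signal features (default
#'   evenly spaced from 1 to 3).
#' @param phases Numeric vector of phases in `[0, 1)` recycled over signal
#'   features, `"spread"` (evenly spaced, the default) or `"uniform"`
#'   (random).
#' @param noise_sd Residual standard deviation, > 0 (default 0.5).
#' @param group_shift_sd Standard deviation of additive per-(group,
#'   feature) baselines (default 0).
#' @param waveform `"cosine"` or `"spline-perturbed"` (adds a random
#'   second-harmonic to each signal feature so waveforms are periodic but
#'   not sinusoidal).
#' @param missing_rate Fraction of entries masked to `NA` (default 0).
#' @param seed Integer seed; the simulation is fully reproducible and does
#'   not disturb the global RNG state.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_signal_features = 20, n_noise_features = 480,
                       n_timepoints = 12, n_replicates = 2, n_groups = 3,
                       amplitudes = seq(1, 3, length.out = n_signal_features),
                       phases = "spread", noise_sd = 0.5, group_shift_sd = 0,
                       waveform = c("cosine", "spline-perturbed"),
                       missing_rate = 0, seed = 1) {
  waveform <- match.arg(waveform)
  cfg <- list(n_signal_features = as.integer(n_signal_features),
              n_noise_features = as.integer(n_noise_features),
              n_timepoints = as.integer(n_timepoints),
              n_replicates = as.integer(n_replicates),
              n_groups = as.integer(n_groups),
              amplitudes = amplitudes, phases = phases,
              noise_sd = noise_sd, group_shift_sd = group_shift_sd,
              waveform = waveform, missing_rate = missing_rate,
              seed = as.integer(seed))
  counts <- c(cfg$n_signal_features, cfg$n_noise_features, cfg$n_timepoints,
              cfg$n_replicates, cfg$n_groups)
  if (any(counts < 0)) stop("all counts in the configuration must be >= 0")
  if (cfg$n_timepoints < 1 || cfg$n_groups < 1 || cfg$n_replicates < 1) {
    stop("need at least one time-point, replicate and group")
  }
  if (!is.numeric(noise_sd) || noise_sd <= 0) stop("`noise_sd` must be > 0")
  if (group_shift_sd < 0) stop("`group_shift_sd` must be >= 0")
  if (missing_rate < 0 || missing_rate >= 1) stop("`missing_rate` must be in [0, 1)")
  structure(cfg, class = "sim_config")
}

#' Simulate a multi-group oscillatory dataset
#'
#' Generates data under the design in a [sim_config()]: the value of signal
#' feature j at time t in group g is
#' `baseline[g, j] + A_j * waveform(t - phi_j) + N(0, noise_sd^2)`, noise
#' features are `baseline[g, j] + N(0, noise_sd^2)`, and entries are masked
#' at `missing_rate`. Ground truth (which features carry signal, their
#' amplitudes and phases) is returned alongside the data.
#'
#' @param config A [sim_config()].
#' @return An object of class `"ct_sim"`: list with `data` (a
#'   [time_matrix()] on the unit scale), `groups` (character vector) and
#'   `truth` (list: `signal_features`, `amplitude`, `phase`, `noise_sd`,
#'   `waveform`).
#' @examples
#' sim <- simulate_oscillatory(sim_config(seed = 42))
#' dim(sim$data$values)
#' @export
simulate_oscillatory <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, .simulate_impl(config))
}

.simulate_impl <- function(cfg) {
  p_sig <- cfg$n_signal_features
  p_noise <- cfg$n_noise_features
  p <- p_sig + p_noise
  n_per_group <- cfg$n_timepoints * cfg$n_replicates
  n <- n_per_group * cfg$n_groups
  times1 <- rep((seq_len(cfg$n_timepoints) - 1L) / cfg$n_timepoints,
                times = cfg$n_replicates)
  times <- rep(times1, times = cfg$n_groups)
  groups <- rep(sprintf("group%d", seq_len(cfg$n_groups)), each = n_per_group)

  amplitude <- if (p_sig > 0) rep_len(cfg$amplitudes, p_sig) else numeric(0)
  phase <- if (p_sig == 0) {
    numeric(0)
  } else if (identical(cfg$phases, "spread")) {
    (seq_len(p_sig) - 1L) / p_sig
  } else if (identical(cfg$phases, "uniform")) {
    runif(p_sig)
  } else {
    rep_len(cfg$phases %% 1, p_sig)
  }

  feature_ids <- sprintf("g%04d", seq_len(p))
  signal_ids <- feature_ids[seq_len(p_sig)]

  X <- matrix(rnorm(n * p, sd = cfg$noise_sd), n, p)
  if (p_sig > 0) {
    if (cfg$waveform == "cosine") {
      for (j in seq_len(p_sig)) {
        X[, j] <- X[, j] + amplitude[j] * cos(2 * pi * (times - phase[j]))
      }
    } else {
      harm_amp <- runif(p_sig, 0.2, 0.4)
      harm_phase <- runif(p_sig)
      for (j in seq_len(p_sig)) {
        wf <- cos(2 * pi * (times - phase[j])) +
          harm_amp[j] * cos(4 * pi * (times - harm_phase[j]))
        X[, j] <- X[, j] + amplitude[j] * wf
      }
    }
  }
  if (cfg$group_shift_sd > 0) {
    shifts <- matrix(rnorm(cfg$n_groups * p, sd = cfg$group_shift_sd),
                     cfg$n_groups, p)
    X <- X + shifts[rep(seq_len(cfg$n_groups), each = n_per_group), ]
  }
  if (cfg$missing_rate > 0) {
    X[runif(length(X)) < cfg$missing_rate] <- NA_real_
  }
  observation_ids <- sprintf("%s_t%02d_r%d", groups,
                             round(times * cfg$n_timepoints),
                             rep(rep(seq_len(cfg$n_replicates),
                                     each = cfg$n_timepoints),
                                 times = cfg$n_groups))
  data <- time_matrix(X, times, period = 1, feature_ids = feature_ids,
                      observation_ids = observation_ids)
  structure(
    list(data = data, groups = groups,
         truth = list(signal_features = signal_ids, amplitude = amplitude,
                      phase = phase, noise_sd = cfg$noise_sd,
                      waveform = cfg$waveform),
         config = cfg),
    class = "ct_sim"
  )
}

#' @export
print.ct_sim <- function(x, ...) {
  cat(sprintf("<ct_sim> %d observations x %d features (%d signal), %d groups, seed %d\n",
              nrow(x$data$values), ncol(x$data$values),
              length(x$truth$signal_features), x$config$n_groups, x$config$seed))
  invisible(x)
}

#' The canonical synthetic benchmark
#'
#' A fixed design used throughout the package's tests and examples: 20
#' sinusoidal signal features with phases evenly spread over the cycle and
#' amplitudes from 1 to 3, 480 pure-noise features, 12 time-points per
#' cycle x 2 replicates x 3 groups (72 observations x 500 features),
#' residual standard deviation 0.5, no group baseline shifts and no missing
#' data — the shape of a batch-corrected multi-organ circadian time course
#' sampled every 2 h.
#'
#' @param seed Integer seed.
#' @return A `"ct_sim"` (see [simulate_oscillatory()]).
#' @examples
#' sim <- default_benchmark(seed = 7)
#' table(sim$groups)
#' @export
default_benchmark <- function(seed = 1) {
  simulate_oscillatory(sim_config(seed = seed))
}
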