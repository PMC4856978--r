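# circatime

`circatime` predicts the value of a periodic variable — circadian time is
the motivating case — from a single high-dimensional observation such as a
gene-expression profile. It is aimed at chronobiologists and genomics
analysts who have a training time course (observations × features with a
known sampling time for each observation) and want a sparse, interpretable
predictor that can time-stamp new samples from their molecular state alone.

## The method

Time is rescaled to the unit circle, t ∈ [0, 1) with 0 ≡ 1. Training works
on a matrix X ∈ ℝ^{n×p} and times T ∈ [0,1)^n:

1. **Per-feature periodic densities.** Each feature j gets a time-dependent
   mean f_j(t), fitted as a periodic smoothing spline (harmonic basis,
   curvature penalty ∫f″² chosen by GCV), and a constant variance
   s_j² = RSS_j/n about that curve. The conditional density of feature j
   given time is modeled as N(f_j(t), s_j²).
2. **Pattern matrix.** The mean curves are discretized at m evenly spaced
   time-points τ_i = (i−1)/m, centered, and scaled by s_j:
   z_ij = (f_j(τ_i) − f̄_j)/s_j, so each feature is expressed in
   signal-to-noise units. Z is m × p.
3. **Sparse principal components.** A penalized matrix decomposition of Z —
   alternating maximization of uᵀZv under ‖u‖₂ ≤ 1, ‖v‖₂ ≤ 1,
   ‖v‖₁ ≤ `sumabsv`, with orthogonal left vectors across components — yields
   loadings V ∈ ℝ^{p×m} in which each component mixes only a small,
   tunable number of features.
4. **Component densities.** The training data are projected (X̃ = XV) and
   each component's time-dependent mean f̃_k(t) and variance s̃_k² are
   fitted exactly as in step 1.
5. **Prediction.** A new observation w is projected (w̃ = wV) and its time
   is the maximizer over the circle of the Gaussian log-likelihood
   L(t | w̃) = Σ_{k=1}^{nSPC} [ −log(s̃_k√(2π)) − (w̃_k − f̃_k(t))²/(2 s̃_k²) ],
   found by a 100-point grid scan plus local refinement of every local
   maximum.

Accuracy of periodic predictions is judged by the wrapped (circular) error,
mapped to the shortest arc in [−0.5, 0.5]; a uniform random guesser has a
mean absolute circular error of 0.25 (6 h on a 24 h clock). The package
also ships a molecular-timetable comparator (cosine-template matching on
high-periodicity, high-variability features), a leave-one-group-out
cross-validation harness, and a synthetic-data generator with known ground
truth.

## Worked example

```r
library(circatime)

sim <- default_benchmark(seed = 42)       # 72 obs x 500 features, 3 groups
model <- ct_train(sim$data, sumabsv = 2, n_spc = 2)
model
#> <ct_model> trained on 72 observations x 500 features
#>   sumabsv = 2, n_spc = 2, m = 12, n_knots = 3, period = 1
#>   predictor uses 12 feature(s): g0005, g0010, g0011, g0012, g0013, ...

round(model$variance_explained[1:3], 3)
#> [1] 0.362 0.200 0.003

head(predict(model, sim$data$values[1:4, ]), 4)
#>   observation_id   time_hat time_hat_units log_likelihood
#> 1  group1_t00_r1 0.01037636     0.01037636     -0.2919586
#> 2  group1_t01_r1 0.09540146     0.09540146     -0.1992008
#> 3  group1_t02_r1 0.16285152     0.16285152     -0.4752115
#> 4  group1_t03_r1 0.23799510     0.23799510     -1.3800399

cv <- leave_one_group_out_cv(sim$data, sim$groups,
                             param_grid = data.frame(sumabsv = 2, n_spc = 2))
cv[[1]]
#> <ct_cv> sumabsv = 2, n_spc = 2: overall MAE = 0.0123 (unit scale)
#>   per-group MAE:
#> group1 group2 group3
#> 0.0116 0.0134 0.0119
```

The 12 selected features are all true oscillators planted by the
simulator; the sample at time 0 is predicted at 0.0104 (≈ 15 min late on a
24 h clock), and held-out-group cross-validation recovers time with a mean
absolute error of 0.0123 cycles ≈ 0.29 h. `time_hat_units` is `time_hat`
multiplied by the training period (here 1; 24 when training data are read
with `--period 24`).

## Command line

A thin `circatime` executable (installed to `exec/`) wraps the same
functions:

```sh
circatime simulate --seed 7 --out-expr X.tsv --out-meta meta.tsv --out-groups groups.tsv
circatime train    --expr X.tsv --meta meta.tsv --sumabsv 2 --nspc 2 --out model.json
circatime predict  --model model.json --expr X.tsv --out predictions.tsv
circatime cv       --expr X.tsv --meta meta.tsv --groups groups.tsv \
                   --sumabsv 1,2,3 --nspc 1,2 --out cv.tsv
```

Expression files are observations × features TSV (use `--transpose` for
feature × sample files); times are given in native units with `--period`
(default 24 h). Models are versioned plain-JSON documents that reload with
bit-identical predictions.

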