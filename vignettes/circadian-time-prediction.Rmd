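---
title: "Predicting circadian time: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting circadian time: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circatime)
```

## The statistical model

`circatime` treats a periodic variable — "time" below, scaled to the unit
circle with $t = 0 \equiv t = 1$ — as the quantity to be predicted from a
single high-dimensional observation. The generative assumption is that each
feature $j$, conditioned on time, is Gaussian with a smooth periodic mean
and a constant variance:

$$x_j \mid t \;\sim\; \mathcal N\!\big(f_j(t),\; s_j^2\big).$$

Both pieces are estimated from a training time course. The mean $f_j$ is a
periodic smoothing spline (see *Numerical choices*); the variance is the
mean squared residual about the fitted curve, $s_j^2 = \mathrm{RSS}_j/n$.
A constant variance is a deliberate simplification: estimating a
time-dependent variance from the handful of replicates per time-point that
real circadian designs afford is fragile, and the constant-variance model
is what the likelihood below needs.

Because $p \gg n$ in genomic applications, prediction does not use the raw
features. The fitted means are discretized at $m$ evenly spaced
time-points, centered, and divided by $s_j$, giving an $m \times p$ pattern
matrix $Z$ in signal-to-noise units — features that oscillate strongly
relative to their noise dominate $Z$ regardless of their raw scale. A
penalized matrix decomposition (PMD) then extracts sparse principal
components: unit-$\ell_2$ loading vectors $v_k$ with $\|v_k\|_1 \le$
`sumabsv`, maximizing $u_k^\top Z v_k$ with the left vectors kept mutually
orthogonal so successive components capture distinct temporal patterns.
Because the decomposition is applied to $Z$ rather than to the data matrix
itself, the components are by construction aligned with time-associated
variation — a supervised use of sparse PCA.

Training data projected onto the loadings give component scores
$\widetilde X = XV$, and each component's time-dependent mean
$\widetilde f_k(t)$ and variance $\widetilde s_k^2$ are estimated by the
same spline procedure. Prediction for an observation $w$ projects it
($\widetilde w = wV$) and maximizes

$$L(t \mid \widetilde w) \;=\; \sum_{k=1}^{\mathrm{nSPC}}
  \left[-\log\!\big(\widetilde s_k \sqrt{2\pi}\big)
  - \frac{(\widetilde w_k - \widetilde f_k(t))^2}{2\widetilde s_k^2}\right]$$

over $t \in [0,1)$. Treating components as independent is not literally
true — they share training data — but the orthogonality of the left vectors
keeps them weakly correlated, and the product form makes the predictor a
transparent sum of per-component evidence.

## Tunable parameters

| Parameter | Default | Meaning and guidance |
|---|---|---|
| `sumabsv` | 2 | $\ell_1$ budget per component (unitless, valid range $[1, \sqrt p]$, `Inf` = ordinary PCA). 1 admits exactly one feature per component; larger values trade interpretability for robustness. |
| `n_spc` | 2 | Components summed in the likelihood. Two suffice to localize a single periodic coordinate (a sine and a cosine phase); more can help with non-sinusoidal dynamics. |
| `m` | 12 | Discretization time-points of $Z$ and the maximum number of components. 12 matches a 2-h sampling grid on a 24-h cycle. |
| `n_knots` | 3 | Harmonic pairs in the spline basis; 3 allows means with up to three oscillations per cycle while the curvature penalty shrinks unneeded ones away. |
| `period` | 24 | Cycle length in the native time units of the input (hours for circadian data); used only at the I/O boundary. |

The molecular-timetable comparator has its own thresholds:
`min_periodicity = 0.8` (cosine correlation) and `min_sd` defaulting to the
90th percentile of feature standard deviations. Variability is judged by
the standard deviation rather than the coefficient of variation because
normalized expression data routinely contain negative values, which make a
mean-relative measure meaningless.

## Numerical choices

**Periodic spline.** The mean curves are fitted in a truncated Fourier
basis, $f(t) = a_0 + \sum_{h\le H} a_h\cos(2\pi h t) + b_h\sin(2\pi h t)$
with $H =$ `n_knots`, penalizing $\int_0^1 f''(t)^2\,dt$ — which is diagonal
in this basis, $\sum_h (2\pi h)^4 (a_h^2+b_h^2)/2$ — with the smoothing
parameter chosen per curve by GCV over a fixed grid
$\lambda \in 10^{\{-12, \dots, 2\}}$. This representation is exactly
periodic (no seam constraint needed), makes the penalized fit a small ridge
solve shared across all features with complete data (hundreds of features
fit in one batched pass), and $H$ is capped at
$\lfloor(\text{distinct times}-1)/2\rfloor$ so the fit stays identifiable
on sparse designs. Fewer than 3 distinct time values for a feature is an
error naming the feature, never a silent skip.

**Variance floor.** A noiseless feature would give $s_j^2 = 0$, breaking
the $1/s_j$ scaling of $Z$ and producing infinite likelihoods, so variances
are floored at $10^{-8}\times(\text{feature range})^2$ (or $10^{-12}$ for a
constant feature).

**PMD iteration.** Each rank-1 factor alternates
$u \leftarrow Zv/\|Zv\|_2$ and
$v \leftarrow S(Z^\top u, \Delta)/\|\cdot\|_2$, where $S$ is entrywise
soft-thresholding and $\Delta \ge 0$ is the smallest threshold meeting the
$\ell_1$ budget, found by bisection (at most 50 iterations, tolerance
$10^{-8}$ on the norm; $\Delta = 0$ whenever the unthresholded vector
already complies). $v$ is initialized at the leading right singular vector
of the (deflated) matrix, so the unpenalized case agrees with the dense
SVD to machine precision; iteration stops when the objective changes by
under $10^{-7}$ or after 100 iterations, with a warning on
non-convergence (observed only for trailing components whose singular
values are nearly tied — directions that carry no usable signal). Signs
are fixed by making the largest-magnitude loading positive, ties going to
the lowest feature index, so decompositions are bit-reproducible.

**Orthogonality.** Before extracting component $k+1$ the working matrix is
$(I - U_kU_k^\top)Z$ with $U_k$ the accumulated left vectors — left-side
deflation that enforces $u_i^\top u_j = 0$ without constraining the
loadings.

**Likelihood maximization.** $L(t\mid\widetilde w)$ is periodic and
multimodal, so a single local search is unsafe. The optimizer evaluates a
100-point even grid, refines *every* cyclic local maximum with bounded
search in its bracketing interval (tolerance $10^{-7}$), and returns the
best candidate; near-ties within $10^{-9}$ in log-likelihood go to the
smallest $t$, making predictions deterministic even for exactly symmetric
likelihoods.

**Missing data.** Training projection uses an available-case rule: a
missing entry contributes zero to the inner product and the score is
divided by the observed loading mass $\sum_{j \in \mathrm{obs}} v_{jk}^2$
(equal to 1 when nothing is missing, since $\|v_k\|_2 = 1$). Test
observations must be complete in the predictor features — the features
actually carrying nonzero loadings — and any violation is an error naming
the observation and feature; missingness elsewhere is harmless and handled
by the same renormalization.

**Circular error.** $\mathrm{err}(t,\hat t)$ is $\hat t - t$ brought into
$[-0.5, 0.5]$ by adding or subtracting one cycle. At a raw difference of
exactly $\pm 0.5$ both wrappings are equidistant and the unwrapped sign is
kept. Absolute errors therefore live in $[0, 0.5]$, and a uniform random
predictor has mean absolute error $0.25$ — the calibration the test suite
verifies by simulation.

## The synthetic benchmark

`default_benchmark()` emulates the statistical shape of a batch-corrected
multi-organ circadian time course: 3 groups (organ stand-ins) × 12
time-points per cycle × 2 replicates (72 observations), 20 sinusoidal
signal features with phases evenly spread over the cycle and amplitudes
1–3, 480 pure-noise features, residual SD 0.5 — per-feature signal-to-noise
between 2 and 6, typical of robustly cycling transcripts after
normalization. Group baseline shifts default to zero because the package
consumes batch-corrected matrices by contract; `group_shift_sd` and a
`"spline-perturbed"` waveform (a random second harmonic per feature) are
available to stress-test robustness to residual organ effects and
non-sinusoidal dynamics.

What passing tests on this generator do show: correct recovery of planted
oscillators, sub-hour cross-validated accuracy at the stated noise level,
and the expected orderings (two components ≥ one component; more
timetable genes ≥ fewer). What they do not show: performance under probe-
level artifacts, heavy-tailed noise, gene–gene correlation beyond the
shared clock, unevenly spaced or sparse sampling, or imperfect batch
correction — real-data properties deliberately outside the generator's
scope.

Problem sizes throughout the tests and the acceptance script (72 × 500
benchmark matrices, 10 seeds, 100-instance optimizer checks,
$10^5$-pair calibration) were chosen as the smallest designs at which the
Monte-Carlo tolerances quoted in the tests are stable.

## Design choices that were genuinely open

* **Spline family.** Any periodic smoother would fit the algorithm's
  contract. The harmonic-basis smoothing spline was chosen for exact
  periodicity, a diagonal curvature penalty, and batched fitting across
  features; `n_knots` plays the role a knot count plays for B-spline
  bases. The default of 3 is a decision, not an inevitability — users with
  sharply non-sinusoidal waveforms should raise it.
* **GCV for smoothing.** Per-feature GCV is the standard automatic choice
  and costs almost nothing here because the design matrix is shared; a
  fixed effective degrees of freedom would be cheaper still but transfers
  poorly across noise levels.
* **Available-case training projection.** With sparse loadings, a missing
  entry in a feature with zero loading should not perturb the score at
  all, and renormalizing by observed loading mass achieves exactly that
  while remaining unbiased when loadings and missingness are independent.
  Test-time strictness is kept: silently imputing a predictor feature
  would hide exactly the failure a user needs to see.
* **Timetable prediction rule.** The comparator scores a candidate time by
  the Pearson correlation between the standardized test values and each
  retained feature's cosine template evaluated at that time. Other
  faithful readings exist (e.g. weighting features by periodicity); the
  correlation rule is scale-free and matches the method's
  template-matching spirit. With a single retained feature a correlation
  is undefined and the negative squared distance is used instead.
* **Grid sizes.** 100 candidate times for the likelihood (its smoothness
  is set by `n_knots` ≤ 3 harmonics, so basins are wide) and 200 phases
  for timetable training, both followed by local refinement; doubling
  either changes benchmark predictions by less than the refinement
  tolerance.

## Limitations

* The Gaussian conditional model is assumed, not checked; heavy-tailed
  features should be transformed before training.
* No confidence statement accompanies a prediction — the log-likelihood
  curve (available via `ct_predict_one(..., keep_curve = TRUE)`) is a
  diagnostic, not a calibrated posterior.
* Batch and covariate correction are out of scope: the model expects
  matrices already normalized across studies/organs.
* Component independence in the likelihood is an approximation; with many
  components (`n_spc` near `m`) the summed likelihood can be overconfident.
* The period must be known; the package predicts phase within a cycle and
  does not estimate period length.
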