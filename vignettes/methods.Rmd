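---
title: "Methods: landmark standardization and the windowing mixed-effects model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landmark standardization and the windowing mixed-effects model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mrwindow)
```

This vignette is the package's account of its own science: the model and
its assumptions, the tunable parameters and their defaults, the numerical
choices, what the synthetic generator does and does not emulate, and the
design decisions that were genuinely open.

## The problem

MR intensities carry no absolute physical unit; two series of the same
sequence and body region can differ by an arbitrary monotone intensity
deformation. Display windowing (level `WL`, width `WW`, equivalently the
limits `LW = WL - WW/2`, `UW = WL + WW/2`) is therefore adjusted per image
by an operator, and operators differ systematically in taste. The package
learns each operator's preference *on a standardized intensity axis* and
transports it to any new image through that image's own histogram.

## Landmark standardization

The intensity of interest (IOI) is the multiset of voxels with intensity
strictly greater than zero — a deliberate strict inequality, since zero
encodes background/air padding in typical magnitude images. Negative
voxels (possible after vendor offset corrections) are likewise excluded.

Landmarks are the IOI percentiles 1, 10, 20, ..., 90, 99, computed by
linear interpolation between order statistics (the type-7 convention of
`quantile`). The convention matters only marginally at clinical voxel
counts; it is fixed here, used identically by the implementation and its
test oracle, and documented so trained scales are reproducible.

A per-condition standard scale is trained by affinely rescaling each
training image's landmark vector so p1 maps to 1 and p99 to 100, then
averaging the rescaled interior landmarks across images; the end nodes
are pinned to exactly 1 and 100. Averaging *rescaled* landmarks (rather
than raw ones) is what keeps the pinned endpoints exact. Training images
whose p1 and p99 coincide carry no usable histogram shape and are
excluded with a warning.

Each image's mapping function interpolates linearly between its 11
landmarks (source knots) and the condition's 11 nodes (target knots).
Three numerical choices:

* **Extrapolation.** Outside the outermost landmarks the terminal
  segment's slope is extended indefinitely. Window limits routinely sit
  below the 1st or above the 99th percentile (a wide window is common for
  low-contrast reading), and clamping would destroy invertibility, so
  slope extension is the only choice compatible with round-tripping
  windows. Limits at or below zero intensity are handled by the same
  rule.
* **Degenerate knots.** Quantized or low-dynamic-range images can repeat
  landmark values. Coincident source knots are merged into one knot
  paired with the mean of their target nodes; if fewer than two distinct
  knots remain the image is unmappable and said so.
* **Inverse.** The inverse is the exact piecewise-linear inverse. If
  target nodes tie (possible only for a degenerate trained scale), the
  tied segment is collapsed to the midpoint of its native preimage before
  inverting; flat segments are otherwise not pointwise invertible.

Windows are standardized limit-wise: convert to (LW, UW), map each limit,
convert back. Monotonicity guarantees the standardized width stays
positive, and the standardize/destandardize composition is the identity
to floating precision (property-tested over random mappings, and measured
at ~1e-13 worst-case relative error over 1000 synthetic images in the
acceptance script).

## The statistical model

Standardized pairs `Y_n = (sWL_n, sWW_n)` follow a bivariate normal with
operator-specific covariance and a mixed-effect mean,

```
Y_n            ~ N2(mu[i_n, j_n, ], Sigma[[i_n]])
mu[i, j, k]    = beta[1, k] + beta[2, k] x1(i) + ... + gamma[i, j, k]
gamma[i, j, k] ~ N(0, tau[j]^2)
```

with operator 1 the dummy-coding reference. The random-effect spread
`tau_j` is indexed by condition only — shared across operators and across
the WL/WW components — following the model's stated structure; a
per-component variant was considered and rejected as an unforced
extension (the printed indexing is unambiguous).

"Non-informative" priors are made concrete as proper, weakly-informative
ones, because improper flats can leave this posterior unstable when cells
are empty:

| parameter | prior | default scale | units |
|---|---|---|---|
| fixed effects `beta` | Normal(0, `beta_sd`²) | 100 | standardized intensity |
| random-effect SD `tau_j` | half-Cauchy(0, `tau_scale`) | 25 | standardized intensity |
| residual SDs of `Sigma_i` | half-Cauchy(0, `sigma_scale`) | 25 | standardized intensity |
| residual correlation | Uniform(−1, 1) | — | — |

On a [1, 100] axis these scales are essentially flat over the plausible
range. `Sigma_i` is given the scale/correlation decomposition rather than
an inverse-Wishart: it keeps the implied marginals interpretable and the
priors independent of each other. `model_spec()` also accepts `fix_tau` /
`fix_sigma`, which freezes those parameters — used for exact-posterior
validation (below) and useful for sensitivity analysis.

Empty operator-by-condition cells are legal: their `gamma` is then
prior-driven and `mu` remains defined through the fixed effects. This is
precisely the mechanism that lets the model propose a window for a
condition an operator never adjusted.

## Estimation

`fit_mcmc()` is a Metropolis-within-Gibbs sampler written for this model:

* `(beta, gamma)` are updated **jointly** as one Gaussian block. They are
  only jointly identified (any constant can move between the intercept
  and the random-effect mean), so alternating updates crawl along a
  posterior ridge; the joint conditional is Gaussian and exact, and with
  `tau`/`Sigma` fixed the sampler draws from the posterior independently
  each sweep.
* `tau_j` (on the log scale) and each `Sigma_i`'s `(log s1, log s2,
  atanh rho)` are updated by univariate slice sampling with stepping-out
  — tuning-free and rejection-free.
* All likelihood terms reduce to per-cell sufficient statistics (counts,
  sums, cross-products), so one sweep costs O(I·J) regardless of the
  number of records; fitting 750 records takes ~30 s at the default
  budget on one core.

The default budget is 4 chains × (1000 warmup + 2500 retained sweeps), no
thinning — ample for this sampler's near-iid mixing at desk scale. A
`"reference"` profile provides a conservative high-budget run (4 chains,
50000 iterations each of which 1000 warmup, thinned by 5) in the style of
HMC budgets used for clinical-scale fits; its iteration count is total
per chain including warmup.

Convergence uses split-Rhat (each chain halved), strictly more
conservative than the classic statistic because within-chain drift also
inflates it; the verdict is `all split-Rhat < 1.1`, checked for every
stored scalar including the derived `mu`. Quantities held fixed have zero
variance and are reported as exactly 1. Note that for *identical* chains
split-Rhat sits at 1 + O(1/n), not exactly 1 — its half-vs-half
comparison sees ordinary sampling variation.

`extract_mu_hat()` averages the per-draw `mu` reconstruction; a
non-positive posterior-mean width is flagged loudly (it would indicate a
badly specified fit), never silently clamped.

### Validation strategy

Three layers, all in the test suite and acceptance script:

1. **Exact posterior.** With `fix_tau`/`fix_sigma`, the posterior of
   `(beta, gamma)` is exactly Gaussian; an independently coded dense
   row-level construction gives the posterior mean in closed form, and
   MCMC means must agree within 3 Monte-Carlo standard errors.
2. **Parameter recovery.** Data simulated from the generative model at
   I = 3, J = 5 must give central 99% posterior intervals covering ≥ 95%
   of the 30 cell means at n = 50 per cell, with RMSE decreasing over
   n ∈ {10, 50, 200}.
3. **End-to-end.** The full image pipeline on the default scenario must
   converge and beat the naive baseline (below).

## Prediction

For a new image the operator's `(soWL, soWW)` is looked up, converted to
limits, pushed through the inverse map built from *that image's*
landmarks, and converted back. Every intermediate (so-limits, o-limits)
is kept in the output for audit. Two policies:

* Unknown conditions never substitute silently. The user may supply an
  explicit fallback map (e.g. a T1 finger image borrowing T1 knee
  parameters, two conditions with similar signal-intensity
  distributions); using it logs a warning.
* A predicted native width below 1 intensity unit is clamped to 1 with a
  warning — display hardware needs positive width; the threshold is the
  smallest representable integer window.

## Evaluation

MRE (%), MAE (native units) and Pearson's ρ are computed for WL and WW
separately, stratified by operator, plus an average row. Two documented
choices: the covariance and standard deviations in ρ use population
(1/T) normalization consistently (the choice cancels); and the average
row is the unweighted mean of operator-level metrics, matching a
per-operator report layout (the pooled alternative differs only when
strata sizes differ). The naive baseline pools operators within condition
— it is the "one optimal window per condition" assumption the framework
is designed to replace — while evaluation stays operator-stratified.

## The synthetic generator

`sim_scenario()` fixes the study conditions once:

* **Images:** per-condition log-normal mixtures (1–2 components,
  `meanlog` 5–7, `sdlog` 0.25–0.8), 20000 voxels per series, and a
  per-image lognormal gain (sdlog 0.25) plus normal offset (sd 25) so no
  two images share a native scale and some voxels land at or below zero.
* **Behavior:** operators window every series; standardized draws follow
  the generative model with fixed effects (48, 60) and operator contrasts
  of ±5–10 standardized units, `tau` between 3 and 6, residual SDs 2–5
  with correlations 0.35–0.6 (WL and WW co-vary in practice).
* **Scale:** 75 patients × 2 series over 5 conditions at a 7:3
  patient-level split — about 30 records per cell, enough for stable
  fits while keeping a full end-to-end run near half a minute.

Standardized widths are kept positive by rejection: the generator redraws
any pair with `sWW <= 0` and warns if the rejection rate exceeds 10%,
while the fitted model keeps the untruncated bivariate normal — at the
default means the truncated mass is negligible, and this keeps generator
and model consistent with the same distributional assumption. Native
records are produced through each image's own inverse mapping against
pilot scales trained on the training split only, exactly mirroring the
analysis pipeline, so re-standardizing the generated records recovers the
generator's draws to mapping tolerance (a tested loop-closure invariant).

What the generator does **not** emulate: anatomy (histograms only, no
spatial structure), scanner/site effects beyond a global affine, per-slice
windowing, operator drift over time, or heavy-tailed/bimodal observer
behavior. Green tests therefore demonstrate correctness of the machinery
and recoverability under the model's own assumptions — not clinical
performance, which depends on how far real observer behavior departs from
bivariate normality on the standardized axis.

## Known limitations

* A single facility/scanner is implicit; extending the mean structure
  with scanner or site terms is a model change, not a preprocessing one.
* The landmark map assumes the IOI histogram is informative; heavily
  masked or cropped images violate that silently.
* Posterior means are the only quantity transported to the native scale;
  predictive uncertainty of the window itself (from `Sigma_i`) is
  available in the draws but not propagated through the inverse map.
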