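# mrwindow

Predicting observer-specific MRI display windows.

MR images are stored at a higher bit depth than monitors can display, so
every image is "windowed": the stored intensity range is compressed to
display gray levels through a window level `WL` (center) and window width
`WW`. In clinical practice an MRI operator adjusts WL/WW by hand, and
different observers prefer systematically different settings for the same
acquisition sequence and body region. `mrwindow` predicts the window an
individual observer would choose for a new image, using only the WL/WW
values that accumulate in routine practice — no image annotation effort.

## Method

The pipeline has three stages.

**1. Landmark standardization.** Arbitrary scanner units make raw WL/WW
incomparable across images. For each image, the intensity of interest
(IOI) is the set of voxels with intensity > 0, and its 1st, 10th, 20th,
..., 90th and 99th percentiles are landmarks. A per-condition *standard
scale* (11 nodes on [1, 100]) is trained by rescaling each training
image's landmarks so p1 → 1 and p99 → 100 and averaging. Each image then
gets a monotone piecewise-linear *mapping function* pinning its landmarks
to the scale nodes (terminal slopes extended outside the hull). Window
limits

    UW = WL + WW/2,    LW = WL − WW/2

are pushed through the map and converted back, giving standardized
`(sWL, sWW)`.

**2. Bayesian mixed-effects model.** Standardized pairs are modeled as

    (Y_n1, Y_n2) ~ BivariateNormal(μ_{i_n, j_n}, Σ_{i_n})
    μ_{i,j,k} = β_{0,k} + β_{1,k} x_1 + β_{2,k} x_2 + γ_{i,j,k}
    γ_{i,j,k} ~ Normal(0, τ_j²)

with operator `i` dummy-coded as a fixed effect, condition `j`
(sequence × region) entering through an operator-by-condition random
effect, and an operator-specific residual covariance `Σ_i`. The model is
fitted by an in-package Metropolis-within-Gibbs sampler (conjugate joint
Gaussian block for β and γ, slice sampling for τ and the covariance
parameters); convergence requires split-Rhat < 1.1 for every parameter.
Posterior means `μ̂_{i,j,·} = (soWL, soWW)` are the standardized optimal
windows.

**3. Prediction.** For a new image, the observer's `(soWL, soWW)` is
looked up, converted to standardized limits, mapped back through the
*inverse* of the image's own mapping function, and converted to the
native-scale optimal window `(oWL, oWW)`.

Evaluation compares predictions with held-out observer settings via mean
relative error (MRE, %), mean absolute error (MAE, intensity units) and
Pearson's ρ, against a naive baseline that predicts each condition's
training-mean WL/WW for everyone.

## Worked example

A complete synthetic study — generate images and operator behavior with
known truth, split by patient 7:3, standardize, fit, predict the test
images, and score against the naive baseline:

```r
library(mrwindow)
run <- end_to_end_recovery(sim_scenario(), seed = 1)
cat("converged:", run$converged, " max split-Rhat:", round(run$max_rhat, 3), "\n")
cat("RMSE of recovered cell means:", round(run$rmse_mu, 3), "\n")
print(run$report[, c(1:4, 6:8)], row.names = FALSE, digits = 3)
```

```
converged: TRUE  max split-Rhat: 1.017
RMSE of recovered cell means: 0.607

    method operator MRE_WL MAE_WL MRE_WW MAE_WW rho_WW
 framework        1   3.88   25.4   6.48   47.1  0.983
 framework        2   5.49   34.8   6.07   51.5  0.967
 framework        3   2.47   19.5   6.26   39.5  0.963
 framework  average   3.95   26.6   6.27   46.0  0.971
     naive        1  25.50  146.3  23.19  166.2  0.741
     naive        2  31.81  173.1  23.06  190.9  0.642
     naive        3  22.37  160.4  33.82  184.2  0.715
```

All chains converged, the true operator-by-condition cell means are
recovered to about 0.6 standardized units, and the framework's errors are
several-fold lower than the naive baseline's: the baseline can model
neither the per-image intensity scale nor the observer, while the
framework handles both.

The same pipeline is scriptable from a shell via
`inst/cli/mrwindow.R` (`simulate`, `train`, `predict`, `evaluate`
subcommands), and `inst/extdata/example_records.tsv` shows the windowing
record format.

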