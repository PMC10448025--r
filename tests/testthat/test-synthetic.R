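small_scenario <- function(tau = c(2, 3), ...) {
  sim_scenario(patients = 20L, series_per_patient = 2L, n_voxels = 2000L,
               conditions = data.frame(sequence = c("T1WI-SE", "T2WI-TSE"),
                                       region = c("brain", "pelvis")),
               mixtures = list(
                 list(weights = 1, meanlog = 5.5, sdlog = 0.5),
                 list(weights = c(0.6, 0.4), meanlog = c(5.8, 6.8),
                      sdlog = c(0.4, 0.25))),
               tau = tau, ...)
}

test_that("image generation is seeded and follows the mixture recipe", {
  sc <- small_scenario()
  a <- generate_images(sc, seed = 5)
  b <- generate_images(sc, seed = 5)
  expect_equal(length(a), 40)
  expect_identical(a[[7]]$voxels, b[[7]]$voxels)
  expect_false(identical(a[[1]]$voxels,
                         generate_images(sc, seed = 6)[[1]]$voxels))
  # conditions round-robin over series, patients over pairs
  expect_equal(a[[1]]$sequence, "T1WI-SE")
  expect_equal(a[[2]]$sequence, "T2WI-TSE")
  expect_equal(a[[1]]$patient_id, a[[2]]$patient_id)
})

test_that("single-component IOI percentiles match analytic lognormal quantiles", {
  sc <- sim_scenario(patients = 1L, series_per_patient = 1L,
                     conditions = data.frame(sequence = "T1WI-SE",
                                             region = "brain"),
                     mixtures = list(list(weights = 1, meanlog = 6,
                                          sdlog = 0.5)),
                     n_voxels = 100000L, gain_sdlog = 0, offset_sd = 0,
                     beta = rbind(c(48, 60), c(-5, 8), c(6, -10)),
                     tau = 3, Sigma = list(cov_from(2.5, 4, .5),
                                           cov_from(3, 5, .35),
                                           cov_from(2, 3.5, .6)))
  img <- generate_images(sc, seed = 9)[[1]]
  lm <- compute_landmarks(img)
  analytic <- qlnorm(landmark_percentiles / 100, 6, 0.5)
  expect_true(all(abs(lm / analytic - 1) < 0.02))
})

test_that("a large negative offset produces the degenerate-image error path", {
  sc <- small_scenario(offset_sd = 0)
  imgs <- generate_images(sc, seed = 1)
  dead <- imgs[[1]]
  dead$voxels <- dead$voxels - max(dead$voxels) - 1
  expect_error(compute_landmarks(dead), "degenerate image")
})

test_that("windowing generation is seeded, with known truth of the right shape", {
  sc <- small_scenario()
  imgs <- generate_images(sc, seed = 2)
  g1 <- generate_windowing(sc, imgs, seed = 3)
  g2 <- generate_windowing(sc, imgs, seed = 3)
  expect_identical(g1$records, g2$records)
  expect_identical(g1$truth$gamma, g2$truth$gamma)
  expect_equal(dim(g1$truth$mu), c(3, 2, 2))
  expect_equal(nrow(g1$records), 40 * 3)
  expect_true(all(g1$records$WW > 0))
  expect_true(all(g1$truth$standardized$sWW_true > 0))
})

test_that("degenerate noise collapses records onto the operator means", {
  sc <- small_scenario(
    tau = c(1e-9, 1e-9),
    Sigma = list(diag(2) * 1e-12, diag(2) * 1e-12, diag(2) * 1e-12))
  imgs <- generate_images(sc, seed = 4)
  g <- generate_windowing(sc, imgs, seed = 5)
  D <- cbind(1, diag(3)[, -1])
  fixed <- D %*% sc$beta
  for (i in 1:3) {
    sel <- g$truth$standardized$operator == i
    expect_lt(max(abs(g$truth$standardized$sWL_true[sel] - fixed[i, 1])),
              1e-4)
    expect_lt(max(abs(g$truth$standardized$sWW_true[sel] - fixed[i, 2])),
              1e-4)
  }
})

test_that("re-standardizing generated records recovers the generator's draws", {
  # closes the loop between the generator and the standardization module:
  # the pipeline, given only native records and images, must reproduce the
  # standardized pairs the generator drew
  sc <- small_scenario()
  imgs <- generate_images(sc, seed = 6)
  g <- generate_windowing(sc, imgs, seed = 7)
  back <- standardize_records(g$records, imgs, g$scales)
  expect_equal(back$WL, g$truth$standardized$sWL_true, tolerance = 1e-9)
  expect_equal(back$WW, g$truth$standardized$sWW_true, tolerance = 1e-9)
})

test_that("sample means converge to the true cell means (law of large numbers)", {
  tr <- toy_truth(3, 2)
  sim <- simulate_observations(3, 2, 4000, tr$beta, tau = c(3, 5),
                               Sigma = tr$Sigma, seed = 8)
  for (i in 1:3) for (j in 1:2) {
    sel <- sim$records$operator == i &
      sim$records$sequence == paste0("sim-", j)
    se <- sqrt(diag(tr$Sigma[[i]]) / sum(sel))
    got <- c(mean(sim$records$WL[sel]), mean(sim$records$WW[sel]))
    # rejection of non-positive widths leaves a negligible bias here
    expect_true(all(abs(got - sim$mu[i, j, ]) < 4 * se))
  }
})

test_that("scenario validation catches inconsistent recipes", {
  expect_error(small_scenario(tau = c(-1, 2)), "tau")
  expect_error(
    sim_scenario(conditions = data.frame(sequence = "A", region = "r"),
                 mixtures = list(list(weights = c(0.5, 0.4),
                                      meanlog = c(1, 2),
                                      sdlog = c(1, 1))),
                 tau = 1),
    "sum to 1")
  expect_error(small_scenario(n_voxels = 10), "n_voxels")
})
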