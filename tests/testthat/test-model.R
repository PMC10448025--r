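# Independent dense log-density oracle: explicit per-row bivariate-normal
# formula plus explicit prior terms, sharing no code with the package.
oracle_log_density <- function(params, records, conds, spec) {
  I <- spec$I
  D <- cbind(1, diag(I)[, -1, drop = FALSE])
  ll <- 0
  for (r in seq_len(nrow(records))) {
    i <- records$operator[r]
    j <- match(paste(records$sequence[r], records$region[r], sep = "|"),
               conds$condition)
    mu <- c(D[i, ] %*% params$beta[, 1] + params$gamma[i, j, 1],
            D[i, ] %*% params$beta[, 2] + params$gamma[i, j, 2])
    S <- params$Sigma[[i]]
    e <- c(records$WL[r], records$WW[r]) - mu
    ll <- ll - log(2 * pi) - 0.5 * log(det(S)) -
      0.5 * drop(t(e) %*% solve(S) %*% e)
  }
  for (i in seq_len(I)) for (j in seq_len(spec$J)) for (k in 1:2)
    ll <- ll + dnorm(params$gamma[i, j, k], 0, params$tau[j], log = TRUE)
  ll <- ll + sum(dnorm(params$beta, 0, spec$beta_sd, log = TRUE))
  lhc <- function(x, s) log(2) - log(pi * s * (1 + (x / s)^2))
  ll <- ll + sum(lhc(params$tau, spec$tau_scale))
  for (i in seq_len(I)) {
    S <- params$Sigma[[i]]
    ll <- ll + lhc(sqrt(S[1, 1]), spec$sigma_scale) +
      lhc(sqrt(S[2, 2]), spec$sigma_scale) + log(0.5)
  }
  ll
}

random_params <- function(I, J, seed = 1) {
  set.seed(seed)
  mrw_params(beta = matrix(rnorm(2 * I, 0, 5), I, 2),
             gamma = array(rnorm(I * J * 2), c(I, J, 2)),
             tau = runif(J, 0.5, 4),
             Sigma = lapply(seq_len(I), function(i)
               cov_from(runif(1, 1, 4), runif(1, 1, 4), runif(1, -0.8, 0.8))))
}

test_that("design encoding applies the stated dummy coding", {
  tr <- toy_truth(3, 2)
  sim <- simulate_observations(3, 2, 2, tr$beta, tr$tau, tr$Sigma, seed = 1)
  d <- encode_design(sim$records, sim$conditions, I = 3)
  expect_equal(dim(d$Y), c(12, 2))
  first_per_op <- match(1:3, d$i)
  expect_equal(unname(d$X[first_per_op, ]),
               rbind(c(0, 0), c(1, 0), c(0, 1)))
  native <- sim$records; native$frame <- "native"
  expect_error(encode_design(native, sim$conditions), "standardized")
  expect_error(encode_design(sim$records[0, ], sim$conditions),
               "no records")
})

test_that("log density components have their closed forms", {
  spec <- model_spec(I = 1, J = 1)
  p <- mrw_params(beta = matrix(c(3, 7), 1, 2),
                  gamma = array(0, c(1, 1, 2)),
                  tau = 2, Sigma = list(diag(2)))
  rec <- data.frame(patient_id = "P", series_id = "S",
                    sequence = "sim-1", region = "sim", operator = 1L,
                    WL = 3, WW = 7, frame = "standardized",
                    stringsAsFactors = FALSE)
  d <- encode_design(rec, condition_table("sim-1", "sim"), I = 1)
  comp <- log_density(p, d, spec, components = TRUE)
  # observation exactly at its mean, identity covariance
  expect_equal(comp$loglik, -log(2 * pi), tolerance = 1e-12)
  # gamma at zero: sum over (i, j, k) of -log(tau * sqrt(2 pi))
  expect_equal(comp$lp_gamma, 2 * dnorm(0, 0, 2, log = TRUE),
               tolerance = 1e-12)
  # non-positive-definite covariance
  p_bad <- p; p_bad$Sigma <- list(matrix(c(1, 2, 2, 1), 2, 2))
  expect_equal(log_density(p_bad, d, spec), -Inf)
})

test_that("log density matches the independent dense oracle", {
  tr <- toy_truth(3, 3)
  sim <- simulate_observations(3, 3, 4, tr$beta, c(3, 5, 4), tr$Sigma,
                               seed = 11)
  d <- encode_design(sim$records, sim$conditions, I = 3)
  spec <- model_spec(I = 3, J = 3)
  p <- random_params(3, 3, seed = 5)
  expect_equal(log_density(p, d, spec),
               oracle_log_density(p, sim$records, sim$conditions, spec),
               tolerance = 1e-10)
})

test_that("log density is invariant to record order", {
  tr <- toy_truth(3, 2)
  sim <- simulate_observations(3, 2, 5, tr$beta, tr$tau, tr$Sigma, seed = 2)
  spec <- model_spec(I = 3, J = 2)
  p <- random_params(3, 2, seed = 8)
  d1 <- encode_design(sim$records, sim$conditions, I = 3)
  set.seed(1)
  perm <- sample(nrow(sim$records))
  d2 <- encode_design(sim$records[perm, ], sim$conditions, I = 3)
  expect_equal(log_density(p, d1, spec), log_density(p, d2, spec),
               tolerance = 1e-10)
})

test_that("sampling is reproducible bit-for-bit given the seed", {
  tr <- toy_truth(2, 2)
  sim <- simulate_observations(2, 2, 8, tr$beta[1:2, ], tr$tau,
                               tr$Sigma[1:2], seed = 3)
  d <- encode_design(sim$records, sim$conditions, I = 2)
  spec <- model_spec(I = 2, J = 2)
  s <- sampler_settings(chains = 2, warmup = 50, draws = 50)
  f1 <- fit_mcmc(d, spec, s, seed = 99)
  f2 <- fit_mcmc(d, spec, s, seed = 99)
  expect_identical(f1$draws, f2$draws)
})

test_that("near-zero-noise data pins mu-hat to the cell sample means", {
  I <- 3; J <- 2
  tiny <- lapply(1:I, function(i) diag(2) * 1e-6)
  tr <- toy_truth(I, J)
  sim <- simulate_observations(I, J, 20, tr$beta, tau = c(1e-3, 1e-3),
                               Sigma = tiny, seed = 4)
  d <- encode_design(sim$records, sim$conditions, I = I)
  fit <- extract_mu_hat(fit_mcmc(d, model_spec(I = I, J = J),
                                 fast_sampler(), seed = 7))
  cell_means <- array(NA_real_, c(I, J, 2))
  for (i in 1:I) for (j in 1:J) {
    sel <- sim$records$operator == i &
      sim$records$sequence == paste0("sim-", j)
    cell_means[i, j, ] <- c(mean(sim$records$WL[sel]),
                            mean(sim$records$WW[sel]))
  }
  expect_true(max(abs(fit$mu - cell_means)) < 0.1)
})

test_that("empty operator-condition cells are prior-driven, not fatal", {
  tr <- toy_truth(3, 2)
  sim <- simulate_observations(3, 2, 10, tr$beta, tr$tau, tr$Sigma,
                               seed = 6)
  drop <- sim$records$operator == 2 & sim$records$sequence == "sim-2"
  d <- encode_design(sim$records[!drop, ], sim$conditions, I = 3)
  expect_warning(post <- fit_mcmc(d, model_spec(I = 3, J = 2),
                                  fast_sampler(), seed = 8),
                 "empty operator x condition")
  fit <- extract_mu_hat(post)
  expect_true(all(is.finite(fit$mu)))
})

test_that("split-Rhat matches a hand-rolled formula and flags divergence", {
  # identical chains: no between-chain variance; split halves still differ
  # slightly, so split-Rhat sits at 1 + O(1/n) rather than exactly 1
  set.seed(12)
  x <- rnorm(1000)
  a <- array(c(x, x), c(1000, 2, 1), dimnames = list(NULL, NULL, "p"))
  expect_equal(unname(compute_rhat(a)["p"]), 1, tolerance = 5e-3)

  # chains centered at 0 and 10: far beyond the 1.1 threshold
  set.seed(13)
  b <- array(c(rnorm(100, 0), rnorm(100, 10)), c(100, 2, 1),
             dimnames = list(NULL, NULL, "p"))
  expect_gt(unname(compute_rhat(b)["p"]), 3)

  # brute-force split-Rhat on a generic array
  set.seed(14)
  g <- array(rnorm(400, rep(c(0, 0.3), each = 200)), c(200, 2, 1),
             dimnames = list(NULL, NULL, "p"))
  segs <- cbind(g[1:100, 1, 1], g[101:200, 1, 1],
                g[1:100, 2, 1], g[101:200, 2, 1])
  W <- mean(apply(segs, 2, var))
  B <- 100 * var(colMeans(segs))
  expect_equal(unname(compute_rhat(g)["p"]),
               sqrt((99 / 100 * W + B / 100) / W), tolerance = 1e-12)

  expect_error(compute_rhat(array(rnorm(10), c(10, 1, 1))), "2 chains")
})

test_that("mu-hat equals the per-draw reconstruction from beta and gamma", {
  tr <- toy_truth(2, 2)
  sim <- simulate_observations(2, 2, 10, tr$beta[1:2, ], tr$tau,
                               tr$Sigma[1:2], seed = 5)
  d <- encode_design(sim$records, sim$conditions, I = 2)
  post <- fit_mcmc(d, model_spec(I = 2, J = 2),
                   sampler_settings(chains = 2, warmup = 100, draws = 150),
                   seed = 10)
  fit <- extract_mu_hat(post)
  D <- cbind(1, c(0, 1))
  for (i in 1:2) for (j in 1:2) for (k in 1:2) {
    beta_k <- post$draws[, , paste0("beta[1,", k, "]")] +
      D[i, 2] * post$draws[, , paste0("beta[2,", k, "]")]
    mu_draws <- beta_k +
      post$draws[, , paste0("gamma[", i, ",", j, ",", k, "]")]
    expect_equal(mean(mu_draws), fit$mu[i, j, k], tolerance = 1e-10)
    expect_equal(as.vector(mu_draws),
                 as.vector(post$draws[, , paste0("mu[", i, ",", j, ",",
                                                 k, "]")]),
                 tolerance = 1e-10)
  }
})

test_that("relabeling the reference operator leaves mu-hat invariant", {
  tr <- toy_truth(2, 2)
  sim <- simulate_observations(2, 2, 40, tr$beta[1:2, ], c(2, 3),
                               tr$Sigma[1:2], seed = 21)
  swap <- sim$records
  swap$operator <- 3L - swap$operator    # 1 <-> 2
  s <- fast_sampler()
  fit_a <- extract_mu_hat(fit_mcmc(
    encode_design(sim$records, sim$conditions, I = 2),
    model_spec(I = 2, J = 2), s, seed = 30))
  fit_b <- extract_mu_hat(fit_mcmc(
    encode_design(swap, sim$conditions, I = 2),
    model_spec(I = 2, J = 2), s, seed = 31))
  # operator i in fit_a is operator 3-i in fit_b
  expect_lt(max(abs(fit_a$mu[1, , ] - fit_b$mu[2, , ])), 0.5)
  expect_lt(max(abs(fit_a$mu[2, , ] - fit_b$mu[1, , ])), 0.5)
})
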