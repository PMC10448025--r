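#' Simulation scenario with known ground truth
#'
#' Describes a complete synthetic study: per-condition intensity histograms
#' (log-normal mixtures, echoing the right-skewed unimodal/bimodal
#' foreground histograms of clinical MR series), a per-image random
#' gain/offset injecting arbitrary scanner-unit variation, and the true
#' generative parameters of the windowing model in standardized units.
#' The defaults emulate a desk-scale clinical study: 3 operators, 5
#' imaging conditions, 75 patients with 2 series each (30 series per
#' condition, so about 30 records per operator-condition cell), genuine
#' operator heterogeneity in the fixed effects, condition-specific
#' random-effect spreads of a few standardized units, and correlated
#' residual noise as seen between WL and WW in practice.
#'
#' @param I operators. @param patients patient count.
#' @param series_per_patient series per patient (conditions assigned
#'   round-robin over series).
#' @param conditions data.frame with \code{sequence}, \code{region}.
#' @param mixtures list (one per condition) of lists with \code{weights},
#'   \code{meanlog}, \code{sdlog}.
#' @param n_voxels voxels per synthetic series (>= 1000).
#' @param gain_sdlog,offset_sd per-image gain is lognormal(0,
#'   \code{gain_sdlog}), offset is normal(0, \code{offset_sd}); offsets may
#'   push voxels to or below zero, exercising the IOI filter.
#' @param beta true I x 2 fixed-effect matrix (intercept + contrasts).
#' @param tau true length-J random-effect SDs.
#' @param Sigma list of I true 2 x 2 residual covariances.
#' @param train_fraction patient-level training fraction.
#' @return list of class \code{sim_scenario}.
#' @export
sim_scenario <- function(
    I = 3L,
    patients = 75L,
    series_per_patient = 2L,
    conditions = data.frame(
      sequence = c("T1WI-SE", "T2WI-TSE", "DWI-EPI", "T2WI-TSE", "T1WI-SE"),
      region = c("brain", "pelvis", "abdomen", "lumbar-spine", "knee"),
      stringsAsFactors = FALSE),
    mixtures = list(
      list(weights = c(0.55, 0.45), meanlog = c(5.3, 6.2), sdlog = c(0.55, 0.30)),
      list(weights = c(0.70, 0.30), meanlog = c(5.8, 6.9), sdlog = c(0.45, 0.25)),
      list(weights = 1.0, meanlog = 5.0, sdlog = 0.80),
      list(weights = c(0.50, 0.50), meanlog = c(5.5, 6.5), sdlog = c(0.50, 0.35)),
      list(weights = c(0.65, 0.35), meanlog = c(6.0, 7.0), sdlog = c(0.40, 0.30))),
    n_voxels = 20000L,
    gain_sdlog = 0.25,
    offset_sd = 25,
    beta = rbind(c(48, 60), c(-5, 8), c(6, -10)),
    tau = c(3, 5, 4, 6, 3.5),
    Sigma = list(cov_from(2.5, 4.0, 0.50),
                 cov_from(3.0, 5.0, 0.35),
                 cov_from(2.0, 3.5, 0.60)),
    train_fraction = 0.7) {
  J <- nrow(conditions)
  stopifnot(length(mixtures) == J, length(tau) == J, all(tau > 0),
            nrow(beta) == I, ncol(beta) == 2L, length(Sigma) == I,
            n_voxels >= 1000L)
  for (mx in mixtures) {
    if (abs(sum(mx$weights) - 1) > 1e-8)
      stop("mixture weights must sum to 1")
    stopifnot(length(mx$weights) == length(mx$meanlog),
              length(mx$weights) == length(mx$sdlog), all(mx$sdlog > 0))
  }
  for (S in Sigma)
    if (min(eigen(S)$values) <= 0) stop("Sigma must be positive definite")
  structure(list(I = as.integer(I), J = J,
                 patients = as.integer(patients),
                 series_per_patient = as.integer(series_per_patient),
                 conditions = condition_table(conditions$sequence,
                                              conditions$region),
                 mixtures = mixtures, n_voxels = as.integer(n_voxels),
                 gain_sdlog = gain_sdlog, offset_sd = offset_sd,
                 beta = beta, tau = as.numeric(tau), Sigma = Sigma,
                 train_fraction = train_fraction),
            class = "sim_scenario")
}

#' Build a 2x2 covariance from SDs and a correlation
#' @param s1,s2 standard deviations. @param rho correlation.
#' @export
cov_from <- function(s1, s2, rho) {
  stopifnot(s1 > 0, s2 > 0, abs(rho) < 1)
  matrix(c(s1^2, rho * s1 * s2, rho * s1 * s2, s2^2), 2, 2)
}

rmvn2 <- function(n, mu, S) {
  L <- t(chol(S))
  z <- matrix(stats::rnorm(2L * n), 2L, n)
  t(mu + L %*% z)
}

#' Generate synthetic MR series
#'
#' Each series draws its voxels from its condition's log-normal mixture and
#' then applies an image-specific random gain and offset, so no two images
#' share a native intensity scale (the situation the landmark
#' standardization exists to fix). Offsets can push voxels to zero or
#' below, which the IOI filter must exclude.
#'
#' @param scenario a \code{\link{sim_scenario}}.
#' @param seed integer seed; output is deterministic given it.
#' @return list of \code{\link{mr_series}}.
#' @export
generate_images <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "sim_scenario"))
  n_series <- scenario$patients * scenario$series_per_patient
  with_seed(seed, {
    out <- vector("list", n_series)
    for (s in seq_len(n_series)) {
      pat <- (s - 1L) %/% scenario$series_per_patient + 1L
      j <- (s - 1L) %% scenario$J + 1L
      mx <- scenario$mixtures[[j]]
      comp <- sample.int(length(mx$weights), scenario$n_voxels,
                         replace = TRUE, prob = mx$weights)
      vox <- stats::rlnorm(scenario$n_voxels, mx$meanlog[comp],
                           mx$sdlog[comp])
      gain <- stats::rlnorm(1L, 0, scenario$gain_sdlog)
      offset <- stats::rnorm(1L, 0, scenario$offset_sd)
      vox <- gain * vox + offset
      out[[s]] <- mr_series(
        vox,
        series_id = sprintf("S%04d", s),
        patient_id = sprintf("P%03d", pat),
        sequence = scenario$conditions$sequence[j],
        region = scenario$conditions$region[j])
    }
    out
  })
}

#' Generate operator windowing behavior with known truth
#'
#' Draws the random effects \eqn{\gamma_{i,j,k} \sim N(0, \tau_j^2)}, forms
#' the true cell means \eqn{\mu_{i,j,k}}, and for every (series, operator)
#' pair draws a standardized window from the bivariate normal with the
#' operator's covariance; draws with non-positive width are rejected and
#' redrawn (logged; a rejection rate above 10 percent triggers a scenario
#' warning). Each standardized draw is then mapped to the series' native
#' scale through the inverse of that image's own mapping function, built
#' against pilot standard scales trained on the training split only --
#' exactly the transformation the analysis pipeline inverts.
#'
#' @param scenario a \code{\link{sim_scenario}}.
#' @param images output of \code{\link{generate_images}} for the same
#'   scenario.
#' @param seed integer seed.
#' @return list with \code{records} (native-frame windowing records),
#'   \code{split} (patient split), \code{scales} (pilot standard scales)
#'   and \code{truth} (realized \code{gamma}, true \code{mu}, the pre-noise
#'   standardized draws per record, rejection count).
#' @export
generate_windowing <- function(scenario, images, seed = 1L) {
  stopifnot(inherits(scenario, "sim_scenario"))
  I <- scenario$I; J <- scenario$J
  patient_ids <- vapply(images, `[[`, character(1), "patient_id")
  split <- split_by_patient(patient_ids, scenario$train_fraction,
                            seed = seed)
  scales <- train_scale_registry(images[split[patient_ids] == "train"])
  D <- dummy_rows(I)
  fixed <- D %*% scenario$beta                   # I x 2
  with_seed(seed + 1L, {
    gamma <- array(stats::rnorm(I * J * 2L, 0,
                                rep(rep(scenario$tau, each = I), 2L)),
                   c(I, J, 2L))
    mu <- gamma
    mu[, , 1L] <- mu[, , 1L] + fixed[, 1L]
    mu[, , 2L] <- mu[, , 2L] + fixed[, 2L]
    rejections <- 0L
    rows <- vector("list", length(images) * I)
    k <- 0L
    for (s in seq_along(images)) {
      img <- images[[s]]
      key <- condition_key(img$sequence, img$region)
      j <- match(key, scenario$conditions$condition)
      mapping <- build_mapping(compute_landmarks(img), scales[[key]])
      for (i in seq_len(I)) {
        repeat {
          sw <- rmvn2(1L, mu[i, j, ], scenario$Sigma[[i]])
          if (sw[2L] > 0) break
          rejections <- rejections + 1L
        }
        nat <- destandardize_window(sw[1L], sw[2L], mapping)
        k <- k + 1L
        rows[[k]] <- data.frame(
          patient_id = img$patient_id, series_id = img$series_id,
          sequence = img$sequence, region = img$region,
          operator = i, WL = nat$WL, WW = nat$WW, frame = "native",
          sWL_true = sw[1L], sWW_true = sw[2L],
          stringsAsFactors = FALSE)
      }
    }
  })
  all_rows <- do.call(rbind, rows)
  n_rec <- nrow(all_rows)
  if (rejections > 0.10 * n_rec)
    warning("standardized-width rejection rate ",
            round(100 * rejections / (n_rec + rejections), 1),
            "% -- tau/Sigma too large for the mean width")
  records <- all_rows[, c("patient_id", "series_id", "sequence", "region",
                          "operator", "WL", "WW", "frame")]
  truth <- list(gamma = gamma, mu = mu,
                standardized = all_rows[, c("series_id", "operator",
                                            "sWL_true", "sWW_true")],
                rejections = rejections)
  list(records = records, split = split, scales = scales, truth = truth)
}

#' Simulate standardized observations directly from the model
#'
#' Bypasses images entirely: draws the random effects and the standardized
#' window pairs for a balanced design with \code{n_per_cell} records in
#' every operator-condition cell. Used for parameter-recovery studies where
#' only the statistical model is under test.
#'
#' @param I,J design dimensions. @param n_per_cell records per cell.
#' @param beta,tau,Sigma true parameters (as in \code{\link{sim_scenario}}).
#' @param seed integer seed.
#' @return list with \code{records} (standardized-frame record table whose
#'   conditions are labeled \code{sim-1..J}), \code{conditions},
#'   \code{gamma}, \code{mu}.
#' @export
simulate_observations <- function(I, J, n_per_cell, beta, tau, Sigma,
                                  seed = 1L) {
  stopifnot(nrow(beta) == I, length(tau) == J, length(Sigma) == I)
  conds <- condition_table(paste0("sim-", seq_len(J)), "sim")
  D <- dummy_rows(I)
  fixed <- D %*% beta
  with_seed(seed, {
    gamma <- array(stats::rnorm(I * J * 2L, 0,
                                rep(rep(tau, each = I), 2L)), c(I, J, 2L))
    mu <- gamma
    mu[, , 1L] <- mu[, , 1L] + fixed[, 1L]
    mu[, , 2L] <- mu[, , 2L] + fixed[, 2L]
    rows <- list()
    n <- 0L
    for (i in seq_len(I)) for (j in seq_len(J)) {
      Y <- rmvn2(n_per_cell, mu[i, j, ], Sigma[[i]])
      redo <- which(Y[, 2L] <= 0)
      while (length(redo)) {
        Y[redo, ] <- rmvn2(length(redo), mu[i, j, ], Sigma[[i]])
        redo <- redo[Y[redo, 2L] <= 0]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = sprintf("P%d-%d", i, j),
        series_id = sprintf("S%d-%d-%d", i, j, seq_len(n_per_cell)),
        sequence = conds$sequence[j], region = conds$region[j],
        operator = i, WL = Y[, 1L], WW = Y[, 2L], frame = "standardized",
        stringsAsFactors = FALSE)
    }
  })
  list(records = do.call(rbind, rows), conditions = conds,
       gamma = gamma, mu = mu)
}
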