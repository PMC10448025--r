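#' Sampler settings
#'
#' The default profile (4 chains, 1000 warmup sweeps, 2500 retained draws
#' per chain, no thinning) is sized for desk-scale datasets where the Gibbs
#' sweeps mix quickly. The \code{"reference"} profile is a conservative
#' high-budget run for replication-grade fits: 4 chains of 50000 iterations
#' each including 1000 warmup, thinned by 5 (9800 retained draws per
#' chain).
#'
#' @param chains number of chains (>= 2 for convergence diagnostics).
#' @param warmup warmup sweeps discarded per chain.
#' @param draws retained draws per chain (after thinning).
#' @param thin keep every \code{thin}-th post-warmup sweep.
#' @param profile optional name: \code{"default"} or \code{"reference"}.
#' @return list of class \code{sampler_settings}.
#' @export
sampler_settings <- function(chains = 4L, warmup = 1000L, draws = 2500L,
                             thin = 1L, profile = NULL) {
  if (!is.null(profile)) {
    profile <- match.arg(profile, c("default", "reference"))
    if (profile == "reference") { warmup <- 1000L; thin <- 5L; draws <- 9800L }
  }
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 draws = as.integer(draws), thin = as.integer(thin)),
            class = "sampler_settings")
}

# 2x2 inverse and log determinant
inv2 <- function(S) {
  d <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
  list(W = matrix(c(S[2, 2], -S[1, 2], -S[2, 1], S[1, 1]), 2, 2) / d,
       logdet = log(d))
}

# Log likelihood of all records of operator i from cell-level sufficient
# statistics; M1/M2 are the length-J component means for that operator.
op_loglik <- function(st, i, M1, M2, S) {
  iv <- inv2(S); W <- iv$W
  n <- st$n[i, ]; S1 <- st$S1[i, ]; S2 <- st$S2[i, ]
  quad <- W[1, 1] * st$SS11[i, ] + 2 * W[1, 2] * st$SS12[i, ] +
    W[2, 2] * st$SS22[i, ] -
    2 * (M1 * (W[1, 1] * S1 + W[1, 2] * S2) +
           M2 * (W[1, 2] * S1 + W[2, 2] * S2)) +
    n * (W[1, 1] * M1^2 + 2 * W[1, 2] * M1 * M2 + W[2, 2] * M2^2)
  Ni <- sum(n)
  -Ni * log(2 * pi) - 0.5 * Ni * iv$logdet - 0.5 * sum(quad)
}

# Univariate slice sampler with stepping out (Neal 2003)
slice1 <- function(x0, logf, w = 1, m = 50L) {
  fx0 <- logf(x0)
  logy <- fx0 - stats::rexp(1)
  u <- stats::runif(1) * w
  L <- x0 - u; R <- L + w
  J <- floor(stats::runif(1) * m); K <- m - 1L - J
  while (J > 0 && logf(L) > logy) { L <- L - w; J <- J - 1L }
  while (K > 0 && logf(R) > logy) { R <- R + w; K <- K - 1L }
  repeat {
    x1 <- stats::runif(1, L, R)
    if (logf(x1) >= logy) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}

sigma_from <- function(ls1, ls2, z) {
  s1 <- exp(ls1); s2 <- exp(ls2); rho <- tanh(z)
  matrix(c(s1^2, rho * s1 * s2, rho * s1 * s2, s2^2), 2, 2)
}

#' Fit the windowing model by MCMC
#'
#' Metropolis-within-Gibbs sampler for the bivariate-normal mixed-effects
#' model: the fixed effects and the random effects have conjugate Gaussian
#' full conditionals (updated jointly per block), while the random-effect
#' SDs \eqn{\tau_j} and the covariance parameters of each \eqn{\Sigma_i}
#' (log scales and atanh correlation) are updated by univariate slice
#' sampling. The likelihood enters every update through cell-level
#' sufficient statistics, so one sweep costs O(I x J) regardless of the
#' number of records. Empty (operator, condition) cells are allowed: their
#' random effect is drawn from its prior, which is exactly the mechanism by
#' which the model predicts a condition an operator never adjusted.
#'
#' @param design an \code{\link{encode_design}} observation matrix.
#' @param spec a \code{\link{model_spec}}.
#' @param settings a \code{\link{sampler_settings}}.
#' @param seed integer seed; draws are reproducible bit-for-bit given it.
#' @return object of class \code{mrw_posterior}: \code{draws} (array
#'   draw x chain x parameter, including the derived cell means
#'   \code{mu[i,j,k]}), \code{param_names}, plus the spec, settings, seed
#'   and condition table.
#' @export
fit_mcmc <- function(design, spec, settings = sampler_settings(),
                     seed = 1L) {
  stopifnot(inherits(design, "mrw_design"), inherits(spec, "mrw_model_spec"))
  I <- spec$I; J <- spec$J
  if (design$I != I || design$J != J)
    stop("design dimensions do not match the model spec")
  st <- suff_stats(design)
  if (any(st$n == 0))
    warning(sum(st$n == 0), " empty operator x condition cell(s); their ",
            "random effects are prior-driven")
  D <- dummy_rows(I)
  n_par <- 2L * I + 2L * I * J + J + 3L * I + 2L * I * J
  pn <- c(paste0("beta[", rep(seq_len(I), 2), ",", rep(1:2, each = I), "]"),
          paste0("gamma[", rep(seq_len(I), J * 2), ",",
                 rep(rep(seq_len(J), each = I), 2), ",",
                 rep(1:2, each = I * J), "]"),
          paste0("tau[", seq_len(J), "]"),
          paste0("sigma1[", seq_len(I), "]"),
          paste0("sigma2[", seq_len(I), "]"),
          paste0("rho[", seq_len(I), "]"),
          paste0("mu[", rep(seq_len(I), J * 2), ",",
                 rep(rep(seq_len(J), each = I), 2), ",",
                 rep(1:2, each = I * J), "]"))
  stopifnot(length(pn) == n_par)
  draws <- array(NA_real_, c(settings$draws, settings$chains, n_par),
                 dimnames = list(NULL, NULL, pn))

  # data-driven starting center: operator component means and pooled
  # within-cell covariance
  Ni <- rowSums(st$n)
  m_op <- cbind(rowSums(st$S1) / pmax(Ni, 1), rowSums(st$S2) / pmax(Ni, 1))
  pooled_var <- max(1e-2, mean(
    (sum(st$SS11) - sum(st$S1^2 / pmax(st$n, 1))) / max(design$N - 1, 1) +
      (sum(st$SS22) - sum(st$S2^2 / pmax(st$n, 1))) / max(design$N - 1, 1)
  ) / 2)

  with_seed(seed, {
    for (ch in seq_len(settings$chains)) {
      # overdispersed chain initialization around the data-driven center
      beta <- rbind(m_op[1L, ], m_op[-1L, , drop = FALSE] -
                      rep(m_op[1L, ], each = I - 1L))
      beta <- beta + stats::rnorm(2L * I, 0, 1)
      gamma <- array(stats::rnorm(I * J * 2L, 0, 0.5), c(I, J, 2L))
      tau <- if (is.null(spec$fix_tau))
        exp(stats::rnorm(J, log(2), 0.3)) else spec$fix_tau
      if (is.null(spec$fix_sigma)) {
        theta <- matrix(0, I, 3L)   # (log s1, log s2, atanh rho) per op
        theta[, 1L] <- 0.5 * log(pooled_var) + stats::rnorm(I, 0, 0.2)
        theta[, 2L] <- 0.5 * log(pooled_var) + stats::rnorm(I, 0, 0.2)
        theta[, 3L] <- stats::rnorm(I, 0, 0.2)
        Sigma <- lapply(seq_len(I), function(i)
          sigma_from(theta[i, 1L], theta[i, 2L], theta[i, 3L]))
      } else {
        theta <- NULL
        Sigma <- spec$fix_sigma
      }
      Winv <- lapply(Sigma, function(S) inv2(S)$W)

      total <- settings$warmup + settings$draws * settings$thin
      kept <- 0L
      n_bg <- 2L * I + 2L * I * J
      for (it in seq_len(total)) {
        # --- (beta, gamma) | tau, Sigma: one joint Gaussian block -------
        # beta and gamma are only jointly identified (mu = fixed + gamma);
        # updating them in a single block removes the posterior ridge that
        # cripples alternating updates.
        P <- matrix(0, n_bg, n_bg)
        P[seq_len(2L * I), seq_len(2L * I)] <- diag(2L * I) / spec$beta_sd^2
        rhs <- numeric(n_bg)
        for (i in seq_len(I)) {
          d <- D[i, ]
          W <- Winv[[i]]
          P[seq_len(2L * I), seq_len(2L * I)] <-
            P[seq_len(2L * I), seq_len(2L * I)] +
            Ni[i] * kronecker(W, outer(d, d))
          rhs[seq_len(2L * I)] <- rhs[seq_len(2L * I)] +
            kronecker(W %*% c(sum(st$S1[i, ]), sum(st$S2[i, ])), d)
          Wd <- kronecker(W, d)                       # 2I x 2 cross block
          for (j in seq_len(J)) {
            rows <- 2L * I + 2L * ((j - 1L) * I + i - 1L) + 1:2
            nij <- st$n[i, j]
            P[rows, rows] <- nij * W + diag(2L) / tau[j]^2
            if (nij > 0) {
              P[seq_len(2L * I), rows] <- nij * Wd
              P[rows, seq_len(2L * I)] <- t(nij * Wd)
              rhs[rows] <- W %*% c(st$S1[i, j], st$S2[i, j])
            }
          }
        }
        U <- chol(P)
        bg <- backsolve(U, forwardsolve(t(U), rhs)) +
          backsolve(U, stats::rnorm(n_bg))
        beta <- matrix(bg[seq_len(2L * I)], I, 2L)
        gamma <- aperm(array(bg[-seq_len(2L * I)], c(2L, I, J)),
                       c(2L, 3L, 1L))      # -> I x J x 2
        M <- D %*% beta                     # I x 2 fixed-effect means

        # --- tau_j | gamma: slice on log tau ----------------------------
        if (is.null(spec$fix_tau)) {
          for (j in seq_len(J)) {
            g2 <- sum(gamma[, j, ]^2)
            lt <- slice1(log(tau[j]), function(lt) {
              tt <- exp(lt)
              -2 * I * lt - g2 / (2 * tt^2) +
                log_half_cauchy(tt, spec$tau_scale) + lt
            })
            tau[j] <- exp(lt)
          }
        }

        # --- Sigma_i | beta, gamma: slice on (log s1, log s2, atanh rho)
        if (is.null(spec$fix_sigma)) {
          for (i in seq_len(I)) {
            M1 <- M[i, 1L] + gamma[i, , 1L]
            M2 <- M[i, 2L] + gamma[i, , 2L]
            for (p in 1:3) {
              th <- theta[i, ]
              theta[i, p] <- slice1(th[p], function(v) {
                th[p] <- v
                S <- sigma_from(th[1L], th[2L], th[3L])
                rho <- tanh(th[3L])
                op_loglik(st, i, M1, M2, S) +
                  log_half_cauchy(exp(th[1L]), spec$sigma_scale) + th[1L] +
                  log_half_cauchy(exp(th[2L]), spec$sigma_scale) + th[2L] +
                  log1p(-rho^2)
              }, w = 0.5)
            }
            Sigma[[i]] <- sigma_from(theta[i, 1L], theta[i, 2L], theta[i, 3L])
            Winv[[i]] <- inv2(Sigma[[i]])$W
          }
        }

        # --- store ------------------------------------------------------
        if (it > settings$warmup &&
            (it - settings$warmup) %% settings$thin == 0L) {
          kept <- kept + 1L
          mu <- mu_from_params(beta, gamma)
          draws[kept, ch, ] <- c(
            as.vector(beta), as.vector(gamma), tau,
            vapply(Sigma, function(S) sqrt(S[1, 1]), numeric(1)),
            vapply(Sigma, function(S) sqrt(S[2, 2]), numeric(1)),
            vapply(Sigma, function(S)
              S[1, 2] / sqrt(S[1, 1] * S[2, 2]), numeric(1)),
            as.vector(mu))
        }
      }
    }
  })
  structure(list(draws = draws, param_names = pn, spec = spec,
                 settings = settings, seed = as.integer(seed),
                 conditions = design$conditions, I = I, J = J),
            class = "mrw_posterior")
}

#' @export
print.mrw_posterior <- function(x, ...) {
  cat("<mrw_posterior> ", dim(x$draws)[1L], " draws x ", dim(x$draws)[2L],
      " chains, ", dim(x$draws)[3L], " parameters (I=", x$I, ", J=", x$J,
      ")\n", sep = "")
  invisible(x)
}
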