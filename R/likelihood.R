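#' Parameter bundle for the windowing model
#'
#' @param beta I x 2 matrix of fixed-effect coefficients (row 1 the
#'   intercept, rows 2..I the operator contrasts; columns are the sWL and
#'   sWW components).
#' @param gamma I x J x 2 array of operator-by-condition random effects.
#' @param tau length-J vector of random-effect SDs, all positive.
#' @param Sigma list of I symmetric positive-definite 2x2 residual
#'   covariance matrices.
#' @return object of class \code{mrw_params}.
#' @export
mrw_params <- function(beta, gamma, tau, Sigma) {
  stopifnot(is.matrix(beta), ncol(beta) == 2L,
            length(dim(gamma)) == 3L, dim(gamma)[3L] == 2L,
            dim(gamma)[1L] == nrow(beta),
            length(tau) == dim(gamma)[2L], all(tau > 0),
            length(Sigma) == nrow(beta))
  structure(list(beta = beta, gamma = gamma, tau = as.numeric(tau),
                 Sigma = Sigma),
            class = "mrw_params")
}

# mu array (I x J x 2) implied by beta and gamma
mu_from_params <- function(beta, gamma) {
  I <- nrow(beta); J <- dim(gamma)[2L]
  D <- dummy_rows(I)
  m <- D %*% beta                       # I x 2 fixed-effect part
  mu <- gamma
  mu[, , 1L] <- mu[, , 1L] + m[, 1L]
  mu[, , 2L] <- mu[, , 2L] + m[, 2L]
  mu
}

log_half_cauchy <- function(x, scale) {
  ifelse(x > 0, log(2 / pi) - log(scale) - log1p((x / scale)^2), -Inf)
}

#' Joint log posterior density of the windowing model
#'
#' Sum of the bivariate-normal log likelihood of every observation at its
#' cell mean, the Gaussian log density of the random effects, and the log
#' priors on the fixed effects, the \eqn{\tau_j} and the covariance
#' parameters (fixed \eqn{\tau}/\eqn{\Sigma} contribute no prior term).
#' Returns \code{-Inf} for a non-positive-definite \eqn{\Sigma_i}.
#'
#' @param params an \code{\link{mrw_params}}.
#' @param design an \code{\link{encode_design}} observation matrix.
#' @param spec a \code{\link{model_spec}}.
#' @param components if TRUE, return the named terms
#'   (\code{loglik}, \code{lp_gamma}, \code{lp_beta}, \code{lp_tau},
#'   \code{lp_sigma}, \code{total}) instead of the total alone.
#' @return scalar log density, or a named list when
#'   \code{components = TRUE}.
#' @export
log_density <- function(params, design, spec, components = FALSE) {
  I <- spec$I; J <- spec$J
  mu <- mu_from_params(params$beta, params$gamma)
  loglik <- 0
  for (i in seq_len(I)) {
    S <- params$Sigma[[i]]
    det_S <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
    if (det_S <= 0 || S[1, 1] <= 0) { loglik <- -Inf; break }
    W <- solve(S)
    rows <- which(design$i == i)
    if (!length(rows)) next
    r1 <- design$Y[rows, 1L] - mu[i, design$j[rows], 1L]
    r2 <- design$Y[rows, 2L] - mu[i, design$j[rows], 2L]
    quad <- W[1, 1] * r1^2 + 2 * W[1, 2] * r1 * r2 + W[2, 2] * r2^2
    loglik <- loglik - length(rows) * (log(2 * pi) + 0.5 * log(det_S)) -
      0.5 * sum(quad)
  }
  tau_rep <- rep(params$tau, each = I)          # tau_j for gamma[, j, k]
  lp_gamma <- sum(stats::dnorm(params$gamma[, , 1L], 0, tau_rep, log = TRUE)) +
    sum(stats::dnorm(params$gamma[, , 2L], 0, tau_rep, log = TRUE))
  lp_beta <- sum(stats::dnorm(params$beta, 0, spec$beta_sd, log = TRUE))
  lp_tau <- if (is.null(spec$fix_tau))
    sum(log_half_cauchy(params$tau, spec$tau_scale)) else 0
  lp_sigma <- if (is.null(spec$fix_sigma)) {
    sum(vapply(params$Sigma, function(S) {
      s1 <- sqrt(S[1, 1]); s2 <- sqrt(S[2, 2])
      rho <- S[1, 2] / (s1 * s2)
      if (abs(rho) >= 1) return(-Inf)
      log_half_cauchy(s1, spec$sigma_scale) +
        log_half_cauchy(s2, spec$sigma_scale) + log(0.5)  # rho ~ U(-1, 1)
    }, numeric(1)))
  } else 0
  out <- list(loglik = loglik, lp_gamma = lp_gamma, lp_beta = lp_beta,
              lp_tau = lp_tau, lp_sigma = lp_sigma)
  out$total <- loglik + lp_gamma + lp_beta + lp_tau + lp_sigma
  if (components) out else out$total
}
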