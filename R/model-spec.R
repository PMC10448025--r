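#' Model specification for the windowing mixed-effects model
#'
#' Standardized window pairs (sWL, sWW) are modeled as bivariate normal with
#' an operator-specific covariance and a mean that decomposes into operator
#' fixed effects (dummy coded against operator 1) plus an
#' operator-by-condition random effect with condition-specific spread:
#' \deqn{Y_n \sim N_2(\mu_{i_n, j_n}, \Sigma_{i_n}), \quad
#'       \mu_{i,j,k} = \beta_{0,k} + \sum_{r} \beta_{r,k} x_r(i) +
#'       \gamma_{i,j,k}, \quad \gamma_{i,j,k} \sim N(0, \tau_{j}^2).}
#' Priors are weakly informative stand-ins for flat priors: Normal(0,
#' \code{beta_sd}^2) on each fixed effect, half-Cauchy(0, \code{tau_scale})
#' on each \eqn{\tau_j}, and \eqn{\Sigma_i} decomposed into per-component
#' scales with half-Cauchy(0, \code{sigma_scale}) priors and a correlation
#' uniform on (-1, 1).
#'
#' @param I number of operators (default 3).
#' @param J number of imaging conditions.
#' @param beta_sd prior SD of the fixed effects (standardized units).
#' @param tau_scale half-Cauchy scale of the random-effect SDs.
#' @param sigma_scale half-Cauchy scale of the residual SDs.
#' @param fix_tau optional numeric vector (length J): hold every
#'   \eqn{\tau_j} fixed at these values instead of sampling them.
#' @param fix_sigma optional list of I fixed 2x2 covariance matrices.
#' @return object of class \code{mrw_model_spec}.
#' @export
model_spec <- function(I = 3L, J, beta_sd = 100, tau_scale = 25,
                       sigma_scale = 25, fix_tau = NULL, fix_sigma = NULL) {
  I <- as.integer(I); J <- as.integer(J)
  stopifnot(I >= 1L, J >= 1L, beta_sd > 0, tau_scale > 0, sigma_scale > 0)
  if (!is.null(fix_tau)) {
    stopifnot(length(fix_tau) == J, all(fix_tau > 0))
    fix_tau <- as.numeric(fix_tau)
  }
  if (!is.null(fix_sigma)) {
    stopifnot(length(fix_sigma) == I)
    for (S in fix_sigma) {
      stopifnot(is.matrix(S), all(dim(S) == 2L),
                isTRUE(all.equal(S, t(S))), min(eigen(S)$values) > 0)
    }
  }
  structure(list(I = I, J = J, beta_sd = beta_sd, tau_scale = tau_scale,
                 sigma_scale = sigma_scale, fix_tau = fix_tau,
                 fix_sigma = fix_sigma),
            class = "mrw_model_spec")
}

# Dummy-coding design row for operator i: intercept plus I-1 indicators,
# operator 1 is the reference (all indicators zero).
dummy_rows <- function(I) {
  D <- cbind(1, diag(I)[, -1L, drop = FALSE])
  rownames(D) <- paste0("op", seq_len(I))
  D
}

#' Encode standardized records as a model observation matrix
#'
#' Stacks the standardized (sWL, sWW) pairs with their operator and
#' condition indices and the dummy coding of the operator (operator 1 is the
#' reference level: all indicators zero; operator 2 is (1, 0), operator 3 is
#' (0, 1), and so on).
#'
#' @param records windowing records in the \code{"standardized"} frame.
#' @param conditions a \code{\link{condition_table}}; defaults to the
#'   conditions present in \code{records}.
#' @param I operator count.
#' @return list of class \code{mrw_design}: \code{Y} (N x 2 matrix),
#'   \code{i}, \code{j} (index vectors), \code{X} (N x (I-1) dummy matrix),
#'   \code{I}, \code{J}, \code{N}, \code{conditions}.
#' @export
encode_design <- function(records, conditions = conditions_from_records(records),
                          I = 3L) {
  if (nrow(records) == 0L) stop("no records to encode")
  stop_if_not_frame(records, "standardized")
  I <- as.integer(I)
  if (any(records$operator < 1L | records$operator > I))
    stop("operator index outside 1..", I)
  j <- condition_index(conditions, records$sequence, records$region)
  if (anyNA(j)) stop("record condition not present in the condition table")
  Y <- cbind(sWL = records$WL, sWW = records$WW)
  if (anyNA(Y)) stop("missing values in standardized windows")
  D <- dummy_rows(I)
  structure(list(Y = Y, i = as.integer(records$operator), j = as.integer(j),
                 X = D[records$operator, -1L, drop = FALSE],
                 I = I, J = nrow(conditions), N = nrow(Y),
                 conditions = conditions),
            class = "mrw_design")
}

# Cell-level sufficient statistics: everything the likelihood needs reduces
# to per-(operator, condition) counts, sums and cross-product sums, making
# each MCMC sweep O(I*J) irrespective of N.
suff_stats <- function(design) {
  I <- design$I; J <- design$J
  idx <- factor(paste(design$i, design$j),
                levels = as.vector(outer(seq_len(I), seq_len(J), paste)))
  agg <- function(v) matrix(vapply(split(v, idx), sum, numeric(1)), I, J)
  y1 <- design$Y[, 1L]; y2 <- design$Y[, 2L]
  list(n = agg(rep(1, design$N)),
       S1 = agg(y1), S2 = agg(y2),
       SS11 = agg(y1 * y1), SS12 = agg(y1 * y2), SS22 = agg(y2 * y2))
}
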