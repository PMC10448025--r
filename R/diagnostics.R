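#' Split-Rhat convergence diagnostic
#'
#' The Gelman-Rubin potential scale reduction factor computed after
#' splitting each chain in half, so within-chain drift inflates the
#' statistic just as between-chain disagreement does. Values below 1.1 for
#' every scalar parameter are taken as converged. Parameters with zero
#' variance across all draws (e.g. quantities held fixed) are reported as
#' exactly 1.
#'
#' @param samples an \code{\link{fit_mcmc}} posterior, or a draws array
#'   (draw x chain x parameter).
#' @param threshold convergence threshold (default 1.1).
#' @return named numeric vector of Rhat values with attributes
#'   \code{converged} (logical: all below \code{threshold}) and
#'   \code{max_rhat}.
#' @export
compute_rhat <- function(samples, threshold = 1.1) {
  draws <- if (inherits(samples, "mrw_posterior")) samples$draws else samples
  stopifnot(length(dim(draws)) == 3L)
  n <- dim(draws)[1L]; m <- dim(draws)[2L]
  if (m < 2L) stop("split-Rhat needs at least 2 chains")
  if (n < 4L) stop("split-Rhat needs at least 4 draws per chain")
  half <- n %/% 2L
  rhat <- vapply(seq_len(dim(draws)[3L]), function(p) {
    # split each chain into halves -> 2m sequences of length half
    segs <- cbind(draws[seq_len(half), , p, drop = TRUE],
                  draws[(n - half + 1L):n, , p, drop = TRUE])
    mns <- colMeans(segs)
    vars <- apply(segs, 2L, stats::var)
    W <- mean(vars)
    B <- half * stats::var(mns)
    if (W == 0) return(1)
    sqrt(((half - 1) / half * W + B / half) / W)
  }, numeric(1))
  names(rhat) <- dimnames(draws)[[3L]]
  attr(rhat, "max_rhat") <- max(rhat)
  attr(rhat, "converged") <- all(rhat < threshold)
  rhat
}

# Monte Carlo standard error of the mean by non-overlapping batch means,
# pooled across chains.
mcse_mean <- function(x) {
  if (is.matrix(x)) {
    per <- apply(x, 2L, mcse_mean)
    sqrt(sum(per^2)) / ncol(x)
  } else {
    n <- length(x)
    b <- max(2L, floor(sqrt(n)))
    nb <- n %/% b
    bm <- colMeans(matrix(x[seq_len(nb * b)], b, nb))
    stats::sd(bm) / sqrt(nb)
  }
}
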