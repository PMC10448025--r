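#' Extract the standardized optimal windows from a posterior
#'
#' The posterior mean of each cell mean \eqn{\mu_{i,j,k}} is the
#' standardized optimal window for operator i under condition j:
#' component k = 1 is soWL, k = 2 is soWW. Cells without data are still
#' defined (through the fixed effects and the random-effect prior).
#' Convergence is checked with split-Rhat first; a failed check attaches a
#' warning but the extraction proceeds, as does a non-positive soWW (which
#' is flagged, never silently dropped).
#'
#' @param samples an \code{\link{fit_mcmc}} posterior.
#' @return object of class \code{mrw_fit}: \code{mu} (I x J x 2 array of
#'   posterior means), \code{table} (data.frame operator, sequence, region,
#'   soWL, soWW), \code{mcse} (same shape as \code{mu}), and a
#'   \code{convergence} report (max Rhat, verdict, settings, seed).
#' @export
extract_mu_hat <- function(samples) {
  stopifnot(inherits(samples, "mrw_posterior"))
  I <- samples$I; J <- samples$J
  rhat <- compute_rhat(samples)
  if (!attr(rhat, "converged"))
    warning("chains not converged: max split-Rhat = ",
            format(attr(rhat, "max_rhat"), digits = 4))
  idx <- grep("^mu\\[", samples$param_names)
  mu_draws <- samples$draws[, , idx, drop = FALSE]
  mu <- array(apply(mu_draws, 3L, mean), c(I, J, 2L))
  mcse <- array(apply(mu_draws, 3L, function(d) mcse_mean(d)), c(I, J, 2L))
  if (any(mu[, , 2L] <= 0))
    warning("non-positive posterior-mean soWW in ", sum(mu[, , 2L] <= 0),
            " cell(s)")
  conds <- samples$conditions
  tab <- data.frame(
    operator = rep(seq_len(I), J),
    sequence = rep(conds$sequence, each = I),
    region = rep(conds$region, each = I),
    soWL = as.vector(mu[, , 1L]),
    soWW = as.vector(mu[, , 2L]),
    stringsAsFactors = FALSE
  )
  structure(list(mu = mu, mcse = mcse, table = tab, conditions = conds,
                 I = I, J = J,
                 convergence = list(max_rhat = attr(rhat, "max_rhat"),
                                    converged = attr(rhat, "converged"),
                                    settings = samples$settings,
                                    seed = samples$seed)),
            class = "mrw_fit")
}

#' @export
print.mrw_fit <- function(x, ...) {
  cat("<mrw_fit> standardized optimal windows for ", x$I, " operators x ",
      x$J, " conditions\n  max split-Rhat: ",
      format(x$convergence$max_rhat, digits = 4),
      if (x$convergence$converged) " (converged)" else " (NOT converged)",
      "\n", sep = "")
  print(utils::head(x$table, 6L), row.names = FALSE)
  if (nrow(x$table) > 6L) cat("  ... ", nrow(x$table) - 6L, " more rows\n")
  invisible(x)
}

#' Read/write a fitted model
#'
#' The mu-hat table serializes as delimited text (operator, sequence,
#' region, soWL, soWW) with a JSON sidecar (same path + \code{.meta.json})
#' recording the convergence report, sampler settings and seed.
#'
#' @param fit an \code{\link{extract_mu_hat}} result.
#' @param path output TSV path.
#' @export
write_fitted <- function(fit, path) {
  utils::write.table(format(fit$table, digits = 17, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(max_rhat = fit$convergence$max_rhat,
               converged = fit$convergence$converged,
               settings = unclass(fit$convergence$settings),
               seed = fit$convergence$seed)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_fitted
#' @return \code{read_fitted}: an \code{mrw_fit} (without posterior MCSEs).
#' @export
read_fitted <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  conds <- condition_table(tab$sequence[tab$operator == 1L],
                           tab$region[tab$operator == 1L])
  I <- max(tab$operator); J <- nrow(conds)
  mu <- array(NA_real_, c(I, J, 2L))
  j <- condition_index(conds, tab$sequence, tab$region)
  mu[cbind(tab$operator, j, 1L)] <- tab$soWL
  mu[cbind(tab$operator, j, 2L)] <- tab$soWW
  meta_path <- paste0(path, ".meta.json")
  conv <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  else list(max_rhat = NA_real_, converged = NA)
  structure(list(mu = mu, mcse = NULL, table = tab, conditions = conds,
                 I = I, J = J, convergence = conv),
            class = "mrw_fit")
}
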