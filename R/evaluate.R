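#' Evaluation metrics: MRE, MAE and Pearson's rho
#'
#' Mean relative error (percent), mean absolute error (native intensity
#' units) and Pearson's correlation coefficient between predicted and
#' observed windowing parameters:
#' \deqn{MRE = \frac{100}{T} \sum_t \left| \frac{\hat y_t - y_t}{y_t}
#'   \right|, \quad MAE = \frac{1}{T} \sum_t |\hat y_t - y_t|, \quad
#'   \rho = \frac{\sigma_{\hat y y}}{\sigma_{\hat y} \sigma_y},}
#' with population (1/T) normalization used consistently in the covariance
#' and both standard deviations (the choice cancels in \eqn{\rho}).
#'
#' @param pred,truth numeric vectors of equal length.
#' @return scalar metric value.
#' @export
mre <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  zero <- which(truth == 0)
  if (length(zero))
    stop("relative error undefined: truth is zero at index ",
         paste(utils::head(zero, 5L), collapse = ", "))
  mean(abs((pred - truth) / truth)) * 100
}

#' @rdname mre
#' @export
mae <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  mean(abs(pred - truth))
}

#' @rdname mre
#' @export
pearson_rho <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  if (length(pred) < 2L) stop("correlation needs at least 2 pairs")
  p <- pred - mean(pred); y <- truth - mean(truth)
  sp <- sqrt(mean(p^2)); sy <- sqrt(mean(y^2))
  if (sp == 0 || sy == 0)
    stop("correlation undefined for a constant input")
  mean(p * y) / (sp * sy)
}

#' Naive per-condition mean baseline
#'
#' The baseline predictor assigns every test series of a condition the
#' arithmetic mean of the native WL and WW over all training records of
#' that condition, pooled across operators; it ignores both the observer
#' and the image's histogram.
#'
#' @param train_records native-frame windowing records of the training set.
#' @return data.frame with \code{sequence}, \code{region}, \code{WL},
#'   \code{WW} (one row per condition) of class \code{naive_baseline}.
#' @export
naive_baseline <- function(train_records) {
  stop_if_not_frame(train_records, "native")
  if (nrow(train_records) == 0L) stop("no training records")
  key <- condition_key(train_records$sequence, train_records$region)
  agg <- lapply(split(train_records, key)[unique(key)], function(d)
    data.frame(sequence = d$sequence[1L], region = d$region[1L],
               WL = mean(d$WL), WW = mean(d$WW),
               stringsAsFactors = FALSE))
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  class(out) <- c("naive_baseline", "data.frame")
  out
}

#' Look up naive predictions for test records
#'
#' @param baseline a \code{\link{naive_baseline}} table.
#' @param records test records (any frame; only condition labels are used).
#' @return data.frame with \code{oWL}, \code{oWW} columns aligned to
#'   \code{records} rows.
#' @export
predict_naive <- function(baseline, records) {
  idx <- match(condition_key(records$sequence, records$region),
               condition_key(baseline$sequence, baseline$region))
  if (anyNA(idx)) {
    missing <- unique(condition_key(records$sequence,
                                    records$region)[is.na(idx)])
    stop("condition(s) absent from the training baseline: ",
         paste(missing, collapse = ", "))
  }
  data.frame(oWL = baseline$WL[idx], oWW = baseline$WW[idx])
}

#' Quantitative evaluation report
#'
#' Computes MRE, MAE and Pearson's rho for WL and WW separately, stratified
#' by operator, plus an across-operator average row (the unweighted mean of
#' the operator-level metrics). Strata with fewer than 2 pairs are skipped
#' with a warning.
#'
#' @param pred data.frame with \code{operator}, \code{oWL}, \code{oWW}.
#' @param truth data.frame with \code{operator}, \code{WL}, \code{WW},
#'   aligned row-for-row with \code{pred}.
#' @param method label for the \code{method} column.
#' @return data.frame with columns \code{method}, \code{operator},
#'   \code{MRE_WL}, \code{MAE_WL}, \code{rho_WL}, \code{MRE_WW},
#'   \code{MAE_WW}, \code{rho_WW}, \code{T}.
#' @export
evaluate_windowing <- function(pred, truth, method = "framework") {
  if (nrow(pred) != nrow(truth)) stop("pred and truth are not aligned")
  if (!all(pred$operator == truth$operator))
    stop("pred and truth operator columns disagree")
  ops <- sort(unique(truth$operator))
  rows <- list()
  for (op in ops) {
    sel <- truth$operator == op
    if (sum(sel) < 2L) {
      warning("operator ", op, " stratum has fewer than 2 pairs; skipped")
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      method = method, operator = as.character(op),
      MRE_WL = mre(pred$oWL[sel], truth$WL[sel]),
      MAE_WL = mae(pred$oWL[sel], truth$WL[sel]),
      rho_WL = pearson_rho(pred$oWL[sel], truth$WL[sel]),
      MRE_WW = mre(pred$oWW[sel], truth$WW[sel]),
      MAE_WW = mae(pred$oWW[sel], truth$WW[sel]),
      rho_WW = pearson_rho(pred$oWW[sel], truth$WW[sel]),
      T = sum(sel), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no evaluable strata")
  avg <- data.frame(method = method, operator = "average",
                    t(colMeans(out[, 3:8])), T = sum(out$T),
                    stringsAsFactors = FALSE)
  names(avg) <- names(out)
  rbind(out, avg)
}
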