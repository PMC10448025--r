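#' Resolve the imaging condition of a series against a fitted model
#'
#' Returns the series' own condition index when the model covers it.
#' Otherwise, if the user supplied an explicit fallback map (e.g.
#' \code{"T1WI-SE|finger" = "T1WI-SE|knee"} for a condition with a similar
#' signal-intensity distribution), the substitute's index is returned with
#' a warning; substitution is never automatic.
#'
#' @param series an \code{\link{mr_series}}.
#' @param conditions the fitted model's \code{\link{condition_table}}.
#' @param fallback optional named character vector mapping unknown
#'   \code{"sequence|region"} keys to modeled ones.
#' @return integer condition index into \code{conditions}.
#' @export
resolve_condition <- function(series, conditions, fallback = NULL) {
  j <- condition_index(conditions, series$sequence, series$region)
  if (!is.na(j)) return(j)
  key <- condition_key(series$sequence, series$region)
  if (!is.null(fallback) && key %in% names(fallback)) {
    sub <- fallback[[key]]
    j <- match(sub, conditions$condition)
    if (is.na(j))
      stop("fallback target '", sub, "' is not a modeled condition")
    warning("condition '", key, "' not modeled; substituting '", sub, "'")
    return(j)
  }
  stop("unknown imaging condition '", key,
       "' and no fallback mapping provided")
}

#' Predict the optimal native window for a new image
#'
#' Looks up the operator's standardized optimal window (soWL, soWW) for the
#' image's condition in the fitted model, builds the image's own mapping
#' function from its landmarks and the condition's standard scale, and maps
#' the standardized optimal limits back through the inverse of that map to
#' obtain the native-scale optimal window (oWL, oWW). All intermediate
#' quantities are retained so the chain standardized window -> standardized
#' limits -> inverse map -> native limits -> native window is auditable.
#'
#' @param series an \code{\link{mr_series}}.
#' @param operator operator index in \code{1..I}.
#' @param fit an \code{\link{extract_mu_hat}} fitted model.
#' @param scales named scale registry from \code{\link{train_scale_registry}}
#'   (keys \code{"sequence|region"}).
#' @param fallback optional condition fallback map, see
#'   \code{\link{resolve_condition}}.
#' @return data.frame (one row) with \code{series_id}, \code{operator},
#'   \code{sequence}, \code{region}, the prediction \code{oWL}, \code{oWW},
#'   and audit columns \code{soWL}, \code{soWW}, \code{soLW}, \code{soUW},
#'   \code{oLW}, \code{oUW}.
#' @export
predict_window <- function(series, operator, fit, scales, fallback = NULL) {
  stopifnot(inherits(fit, "mrw_fit"))
  operator <- as.integer(operator)
  if (operator < 1L || operator > fit$I)
    stop("operator must be in 1..", fit$I)
  j <- resolve_condition(series, fit$conditions, fallback)
  key <- fit$conditions$condition[j]
  scale <- scales[[key]]
  if (is.null(scale))
    stop("no trained standard scale for condition '", key, "'")
  soWL <- fit$mu[operator, j, 1L]
  soWW <- fit$mu[operator, j, 2L]
  if (!is.finite(soWW) || soWW <= 0)
    stop("fitted soWW for operator ", operator, ", condition '", key,
         "' is not positive")
  mapping <- build_mapping(compute_landmarks(series), scale)
  so_lim <- limits_from_window(soWL, soWW)
  oLW <- map_inverse(mapping, so_lim$LW)
  oUW <- map_inverse(mapping, so_lim$UW)
  ow <- window_from_limits(oLW, oUW)
  if (ow$WW < 1) {
    warning("predicted native window width below 1 intensity unit for ",
            "series ", series$series_id, "; clamped to 1")
    ow$WW <- 1
  }
  data.frame(series_id = series$series_id, operator = operator,
             sequence = series$sequence, region = series$region,
             oWL = ow$WL, oWW = ow$WW,
             soWL = soWL, soWW = soWW,
             soLW = so_lim$LW, soUW = so_lim$UW,
             oLW = oLW, oUW = oUW,
             stringsAsFactors = FALSE)
}

#' Predict windows for many series and operators
#'
#' @param series_list list of \code{\link{mr_series}}.
#' @param operators operator indices to predict for (default all).
#' @inheritParams predict_window
#' @return data.frame with one row per series x operator.
#' @export
predict_windows <- function(series_list, fit, scales,
                            operators = seq_len(fit$I), fallback = NULL) {
  out <- lapply(series_list, function(s) {
    do.call(rbind, lapply(operators, function(op)
      predict_window(s, op, fit, scales, fallback)))
  })
  do.call(rbind, out)
}
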