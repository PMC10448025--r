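#' Piecewise-linear mapping between native intensities and the standard scale
#'
#' The mapping function of one image pins that image's 11 landmark
#' intensities to the 11 nodes of its condition's standard scale and
#' interpolates linearly in between. Outside the outermost landmarks the
#' terminal segment's slope is extended indefinitely, so window limits below
#' the 1st-percentile landmark (including non-positive ones) or above the
#' 99th remain mappable and the map stays invertible. Coincident landmark
#' values (quantized or low-dynamic-range images) are merged into a single
#' knot paired with the mean of their target nodes.
#'
#' @param landmarks numeric vector of 11 landmark intensities
#'   (\code{\link{compute_landmarks}}).
#' @param scale a \code{\link{train_standard_scale}} object, or a numeric
#'   vector of 11 target nodes.
#' @return object of class \code{window_mapping} with knot vectors
#'   \code{source} (native) and \code{target} (standard scale).
#' @export
build_mapping <- function(landmarks, scale) {
  target <- if (inherits(scale, "standard_scale")) scale$nodes else scale
  src <- as.numeric(landmarks)
  tgt <- as.numeric(target)
  if (length(src) != length(tgt))
    stop("landmarks and scale nodes must have equal length")
  if (is.unsorted(src)) stop("landmarks must be non-decreasing")
  # merge coincident source knots: one knot, mean of their targets
  grp <- match(src, src)
  if (anyDuplicated(src)) {
    tgt <- as.numeric(tapply(tgt, grp, mean))
    src <- unique(src)
  }
  if (length(src) < 2L)
    stop("unmappable image: fewer than 2 distinct landmark values")
  structure(list(source = src, target = tgt), class = "window_mapping")
}

#' @export
print.window_mapping <- function(x, ...) {
  cat("<window_mapping> ", length(x$source), " knots, native [",
      format(x$source[1L]), ", ", format(x$source[length(x$source)]),
      "] -> scale [", format(x$target[1L]), ", ",
      format(x$target[length(x$target)]), "]\n", sep = "")
  invisible(x)
}

# Piecewise-linear interpolation through (xs, ys) with terminal-slope
# extension beyond the outermost knots. xs strictly increasing.
pwl <- function(x, xs, ys) {
  n <- length(xs)
  idx <- findInterval(x, xs, all.inside = TRUE)
  x0 <- xs[idx]; x1 <- xs[idx + 1L]
  y0 <- ys[idx]; y1 <- ys[idx + 1L]
  y0 + (x - x0) * (y1 - y0) / (x1 - x0)
}

#' Apply a mapping function
#'
#' @param mapping a \code{\link{build_mapping}} object.
#' @param x native intensities (\code{map_forward}) or standard-scale values
#'   (\code{map_inverse}).
#' @return mapped values; \code{map_forward} followed by \code{map_inverse}
#'   is the identity wherever the local slope is positive.
#' @export
map_forward <- function(mapping, x) pwl(x, mapping$source, mapping$target)

#' @rdname map_forward
#' @export
map_inverse <- function(mapping, x) {
  ys <- mapping$target; xs <- mapping$source
  if (is.unsorted(ys, strictly = TRUE)) {
    # flat target segments are not invertible pointwise; collapse them to a
    # single knot at the mean of their native preimage
    grp <- match(ys, ys)
    xs <- as.numeric(tapply(xs, grp, mean))
    ys <- unique(ys)
    if (length(ys) < 2L)
      stop("mapping is not invertible: constant target nodes")
  }
  pwl(x, ys, xs)
}

#' Window setting / window limit conversions
#'
#' A display window is parameterized either as center/width (window level
#' WL, window width WW) or as its lower/upper intensity limits (LW, UW):
#' \code{UW = WL + WW/2}, \code{LW = WL - WW/2} and inversely
#' \code{WW = UW - LW}, \code{WL = LW + WW/2}. Both directions are exact
#' algebraic inverses and hold in the native and the standardized frame
#' alike.
#'
#' @param WL,WW window level and width (vectorized); \code{WW > 0}.
#' @return \code{limits_from_window}: data.frame with \code{LW}, \code{UW}.
#' @export
limits_from_window <- function(WL, WW) {
  if (any(!is.finite(WW) | WW <= 0)) stop("window width WW must be > 0")
  data.frame(LW = WL - WW / 2, UW = WL + WW / 2)
}

#' @rdname limits_from_window
#' @param LW,UW lower and upper window limits; \code{UW > LW}.
#' @return \code{window_from_limits}: data.frame with \code{WL}, \code{WW}.
#' @export
window_from_limits <- function(LW, UW) {
  if (any(!is.finite(LW) | !is.finite(UW) | UW <= LW))
    stop("window limits must satisfy UW > LW")
  WW <- UW - LW
  data.frame(WL = LW + WW / 2, WW = WW)
}

#' Standardize / de-standardize a window through a mapping function
#'
#' The window is converted to its limits, each limit is passed through the
#' image's piecewise-linear mapping (forward to standardize, inverse to come
#' back to native units), and the mapped limits are converted back to
#' center/width. Monotonicity of the map guarantees the output width stays
#' positive.
#'
#' @param WL,WW window parameters in the input frame (vectorized).
#' @param mapping the image's \code{\link{build_mapping}}.
#' @return data.frame with \code{WL}, \code{WW} in the output frame.
#' @export
standardize_window <- function(WL, WW, mapping) {
  lim <- limits_from_window(WL, WW)
  window_from_limits(map_forward(mapping, lim$LW),
                     map_forward(mapping, lim$UW))
}

#' @rdname standardize_window
#' @export
destandardize_window <- function(WL, WW, mapping) {
  lim <- limits_from_window(WL, WW)
  window_from_limits(map_inverse(mapping, lim$LW),
                     map_inverse(mapping, lim$UW))
}
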