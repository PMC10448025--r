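#' Landmark percentiles of the intensity of interest
#'
#' The intensity of interest (IOI) is the set of voxels with intensity
#' strictly greater than zero; background and any negative values are
#' excluded. Landmarks are the 1st, 10th, 20th, ..., 90th and 99th
#' percentiles of the IOI, computed with linear interpolation between order
#' statistics (\code{\link[stats]{quantile}} type 7). They are the knots of
#' the piecewise-linear standardization map.
#'
#' @name landmarks
NULL

#' The fixed landmark percentiles.
#' @rdname landmarks
#' @export
landmark_percentiles <- c(1, 10, 20, 30, 40, 50, 60, 70, 80, 90, 99)

#' @rdname landmarks
#' @param series an \code{\link{mr_series}} or a numeric vector/array of
#'   voxel intensities.
#' @return \code{ioi}: numeric vector of the strictly positive voxels.
#' @export
ioi <- function(series) {
  vox <- if (inherits(series, "mr_series")) series$voxels else series
  out <- as.numeric(vox[vox > 0])
  if (length(out) == 0L)
    stop("degenerate image: no voxels with intensity > 0",
         if (inherits(series, "mr_series"))
           paste0(" (series ", series$series_id, ")") else "")
  out
}

#' @rdname landmarks
#' @return \code{compute_landmarks}: numeric vector of 11 non-decreasing
#'   native intensities, named by percentile.
#' @export
compute_landmarks <- function(series) {
  x <- ioi(series)
  lm <- stats::quantile(x, probs = landmark_percentiles / 100,
                        names = FALSE, type = 7)
  names(lm) <- paste0("p", landmark_percentiles)
  lm
}

#' Train a per-condition standard scale
#'
#' For each training image of one imaging condition, the landmark vector is
#' rescaled affinely so that its 1st percentile maps to 1 and its 99th to
#' 100; the rescaled interior landmarks are then averaged across images.
#' The resulting 11 nodes (first exactly 1, last exactly 100) are the target
#' knots every image of that condition is mapped onto.
#'
#' @param series_list list of \code{\link{mr_series}} sharing one condition,
#'   or a numeric matrix of landmark vectors (one row per image, 11 cols).
#' @param sequence,region condition labels; taken from the first series if
#'   omitted.
#' @return object of class \code{standard_scale}: condition labels,
#'   \code{percentiles}, \code{nodes} (length 11, in [1, 100]) and
#'   \code{n_images} used.
#' @export
train_standard_scale <- function(series_list, sequence = NULL,
                                 region = NULL) {
  if (is.matrix(series_list)) {
    lm <- series_list
  } else {
    first <- series_list[[1L]]
    if (is.null(sequence)) sequence <- first$sequence
    if (is.null(region)) region <- first$region
    same <- vapply(series_list, function(s)
      s$sequence == sequence && s$region == region, logical(1))
    if (!all(same))
      stop("all series must share the condition ", sequence, "|", region)
    lm <- t(vapply(series_list, compute_landmarks, numeric(11L)))
  }
  if (ncol(lm) != 11L) stop("landmark matrix must have 11 columns")
  span <- lm[, 11L] - lm[, 1L]
  flat <- span <= 0
  if (any(flat)) {
    warning(sum(flat), " image(s) with equal 1st and 99th percentile ",
            "landmarks excluded from scale training")
    lm <- lm[!flat, , drop = FALSE]
    span <- span[!flat]
  }
  if (nrow(lm) == 0L) stop("no usable images to train the standard scale")
  rescaled <- 1 + (lm - lm[, 1L]) / span * 99
  nodes <- colMeans(rescaled)
  nodes[1L] <- 1
  nodes[11L] <- 100
  structure(list(sequence = as.character(sequence),
                 region = as.character(region),
                 percentiles = landmark_percentiles,
                 nodes = as.numeric(nodes),
                 n_images = nrow(lm)),
            class = "standard_scale")
}

#' @export
print.standard_scale <- function(x, ...) {
  cat("<standard_scale> ", x$sequence, " | ", x$region,
      "  (", x$n_images, " training images)\n", sep = "")
  print(round(stats::setNames(x$nodes, paste0("p", x$percentiles)), 3))
  invisible(x)
}

#' Train standard scales for every condition in a dataset
#'
#' @param series_list list of \code{\link{mr_series}} (mixed conditions).
#' @return named list of \code{\link{train_standard_scale}} results, keyed
#'   \code{"sequence|region"}.
#' @export
train_scale_registry <- function(series_list) {
  key <- vapply(series_list, function(s)
    condition_key(s$sequence, s$region), character(1))
  lapply(split(series_list, key)[unique(key)], train_standard_scale)
}

#' Read/write standard scales
#'
#' Scales serialize to delimited text (columns \code{sequence},
#' \code{region}, \code{percentile}, \code{node}, \code{n_images}) so a
#' scale trained in one run is portable to a later predict run.
#'
#' @param scales named list of \code{standard_scale} objects.
#' @param path file path.
#' @return \code{read_scales}: the named scale list.
#' @export
write_scales <- function(scales, path) {
  rows <- do.call(rbind, lapply(scales, function(s)
    data.frame(sequence = s$sequence, region = s$region,
               percentile = s$percentiles, node = s$nodes,
               n_images = s$n_images, stringsAsFactors = FALSE)))
  utils::write.table(format(rows, digits = 17, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scales
#' @export
read_scales <- function(path) {
  rows <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  key <- condition_key(rows$sequence, rows$region)
  out <- lapply(split(rows, key)[unique(key)], function(d) {
    d <- d[order(d$percentile), ]
    structure(list(sequence = d$sequence[1L], region = d$region[1L],
                   percentiles = d$percentile, nodes = d$node,
                   n_images = d$n_images[1L]),
              class = "standard_scale")
  })
  out
}
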