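#' MR series container
#'
#' One acquired series: a voxel intensity array in native scanner units plus
#' its identifiers and imaging condition. The array may have any
#' dimensionality; windowing is applied per series.
#'
#' @param voxels numeric array or vector, non-empty. Negative values are
#'   legal (e.g. after offset correction) but fall outside the intensity of
#'   interest.
#' @param series_id,patient_id opaque identifier strings.
#' @param sequence,region imaging-condition labels.
#' @return object of class \code{mr_series}.
#' @export
mr_series <- function(voxels, series_id, patient_id, sequence, region) {
  if (length(voxels) == 0L) stop("series '", series_id, "' has no voxels")
  structure(list(series_id = as.character(series_id),
                 patient_id = as.character(patient_id),
                 sequence = as.character(sequence),
                 region = as.character(region),
                 voxels = voxels),
            class = "mr_series")
}

#' @export
print.mr_series <- function(x, ...) {
  d <- dim(x$voxels)
  cat("<mr_series> ", x$series_id, " (patient ", x$patient_id, ")\n",
      "  condition: ", x$sequence, " | ", x$region, "\n",
      "  voxels: ", if (is.null(d)) length(x$voxels) else
        paste(d, collapse = " x "),
      ", range [", format(min(x$voxels)), ", ", format(max(x$voxels)), "]\n",
      sep = "")
  invisible(x)
}

#' Read an MR series from disk
#'
#' Supports NIfTI-1 (\code{.nii} / \code{.nii.gz}; the format's own
#' slope/intercept scaling is applied by the reader, nothing else) and a
#' plain-text JSON array-exchange container (\code{.json}) used for portable
#' fixtures: \code{{"dim": [...], "data": [...]}} with data in column-major
#' order.
#'
#' @param path image file.
#' @param series_id,patient_id identifiers to attach.
#' @param sequence,region imaging-condition labels.
#' @return an \code{\link{mr_series}}.
#' @export
read_series <- function(path, series_id, patient_id, sequence, region) {
  if (!file.exists(path)) stop("image file not found: ", path)
  vox <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(obj$data) || length(obj$data) == 0L)
      stop("array-exchange file '", path, "' has no data")
    arr <- as.numeric(obj$data)
    if (!is.null(obj$dim) && length(obj$dim) > 1L) {
      if (prod(obj$dim) != length(arr))
        stop("array-exchange file '", path, "': dim does not match data length")
      array(arr, dim = as.integer(obj$dim))
    } else arr
  } else {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    storage.mode(arr) <- "double"
    arr
  }
  if (length(vox) == 0L) stop("image '", path, "' is empty")
  mr_series(vox, series_id, patient_id, sequence, region)
}

#' Write an MR series
#'
#' Writes NIfTI for \code{.nii}/\code{.nii.gz} paths, otherwise the JSON
#' array-exchange container.
#'
#' @param series an \code{\link{mr_series}}.
#' @param path output file.
#' @export
write_series <- function(series, path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    vox <- series$voxels
    if (is.null(dim(vox))) dim(vox) <- length(vox)
    RNifti::writeNifti(RNifti::asNifti(vox), path)
  } else {
    jsonlite::write_json(
      list(dim = if (is.null(dim(series$voxels))) length(series$voxels)
           else dim(series$voxels),
           data = as.numeric(series$voxels)),
      path, auto_unbox = FALSE, digits = NA)
  }
  invisible(path)
}
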