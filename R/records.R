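#' Column dialect for windowing-record files
#'
#' Windowing records are delimited text with a header, one row per windowed
#' series. The dialect block names the columns so files from any PACS export
#' can be ingested without rewriting them.
#'
#' @param patient_id,series_id,sequence,region,operator,WL,WW,frame column
#'   names in the file.
#' @param sep field separator.
#' @param n_operators number of operators the study uses; operator values
#'   outside \code{1..n_operators} are rejected.
#' @return a list of class \code{record_dialect}.
#' @export
record_dialect <- function(patient_id = "patient_id", series_id = "series_id",
                           sequence = "sequence", region = "region",
                           operator = "operator", WL = "WL", WW = "WW",
                           frame = "frame", sep = "\t", n_operators = 3L) {
  structure(list(patient_id = patient_id, series_id = series_id,
                 sequence = sequence, region = region, operator = operator,
                 WL = WL, WW = WW, frame = frame, sep = sep,
                 n_operators = as.integer(n_operators)),
            class = "record_dialect")
}

#' Read windowing records
#'
#' Reads one row per windowed series: who windowed which series of which
#' imaging condition, and the window level/width they chose. The \code{frame}
#' column says whether WL/WW are in native scanner units or on the
#' standardized landmark scale; files without it are taken as native.
#'
#' @param path delimited text file with a header.
#' @param dialect a \code{\link{record_dialect}}.
#' @return data.frame with columns \code{patient_id}, \code{series_id},
#'   \code{sequence}, \code{region}, \code{operator} (integer), \code{WL},
#'   \code{WW}, \code{frame}.
#' @export
read_windowing_records <- function(path, dialect = record_dialect()) {
  if (!file.exists(path)) stop("windowing-record file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("patient_id", "series_id", "sequence", "region",
            "operator", "WL", "WW")
  for (fld in need) {
    col <- dialect[[fld]]
    if (!col %in% names(raw))
      stop("record file is missing required column '", col, "' (", fld, ")")
  }
  out <- data.frame(
    patient_id = as.character(raw[[dialect$patient_id]]),
    series_id = as.character(raw[[dialect$series_id]]),
    sequence = as.character(raw[[dialect$sequence]]),
    region = as.character(raw[[dialect$region]]),
    operator = as.integer(raw[[dialect$operator]]),
    WL = as.numeric(raw[[dialect$WL]]),
    WW = as.numeric(raw[[dialect$WW]]),
    stringsAsFactors = FALSE
  )
  out$frame <- if (dialect$frame %in% names(raw))
    as.character(raw[[dialect$frame]]) else "native"
  validate_records(out, n_operators = dialect$n_operators)
  out
}

#' Write windowing records
#'
#' @param records a record data.frame as returned by
#'   \code{\link{read_windowing_records}}.
#' @param path output file.
#' @param dialect a \code{\link{record_dialect}} controlling separator and
#'   column names.
#' @export
write_windowing_records <- function(records, path,
                                    dialect = record_dialect()) {
  out <- records[, c("patient_id", "series_id", "sequence", "region",
                     "operator", "WL", "WW", "frame")]
  names(out) <- unlist(dialect[c("patient_id", "series_id", "sequence",
                                 "region", "operator", "WL", "WW", "frame")])
  utils::write.table(format(out, digits = 17, scientific = FALSE,
                            trim = TRUE),
                     path, sep = dialect$sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_records <- function(records, n_operators = 3L) {
  bad <- which(!is.finite(records$WW) | records$WW <= 0)
  if (length(bad))
    stop("invalid window width (WW <= 0) in record row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  bad <- which(is.na(records$operator) | records$operator < 1L |
                 records$operator > n_operators)
  if (length(bad))
    stop("operator out of range 1..", n_operators, " in record row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  invisible(records)
}

stop_if_not_frame <- function(records, frame) {
  if (!all(records$frame == frame))
    stop("records must be in the '", frame, "' frame; found: ",
         paste(unique(records$frame), collapse = ", "))
  invisible(records)
}
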