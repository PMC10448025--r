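#' Imaging-condition registry
#'
#' An imaging condition is a combination of acquisition sequence and body
#' region (e.g. \code{"T1WI-SE"} x \code{"brain"}). Conditions are indexed
#' \code{1..J}; the index is what the mixed-effects model sees, the labels
#' are what records and scale files carry.
#'
#' @param sequence character vector of acquisition-sequence labels.
#' @param region character vector of body-region labels, recycled against
#'   \code{sequence}.
#' @return A data.frame of class \code{condition_table} with columns
#'   \code{sequence}, \code{region}, \code{condition} (the
#'   \code{"sequence|region"} key) and \code{j} (index \code{1..J}).
#' @examples
#' condition_table(c("T1WI-SE", "T2WI-TSE"), c("brain", "pelvis"))
#' @export
condition_table <- function(sequence, region) {
  stopifnot(length(sequence) == length(region) || length(region) == 1L)
  key <- condition_key(sequence, region)
  keep <- !duplicated(key)
  out <- data.frame(
    sequence = as.character(sequence)[keep],
    region = as.character(rep_len(region, length(sequence)))[keep],
    condition = key[keep],
    stringsAsFactors = FALSE
  )
  out$j <- seq_len(nrow(out))
  class(out) <- c("condition_table", "data.frame")
  out
}

#' @rdname condition_table
#' @param records a windowing-record data.frame with \code{sequence} and
#'   \code{region} columns; conditions are interned in order of first
#'   appearance.
#' @export
conditions_from_records <- function(records) {
  condition_table(records$sequence, records$region)
}

condition_key <- function(sequence, region) {
  paste(as.character(sequence), as.character(region), sep = "|")
}

#' Look up condition indices
#'
#' @param conditions a \code{condition_table}.
#' @param sequence,region labels to resolve.
#' @return integer vector of indices \code{j}; \code{NA} where the pair is
#'   not registered.
#' @export
condition_index <- function(conditions, sequence, region) {
  match(condition_key(sequence, region), conditions$condition)
}
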