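#' Patient-level train/test split
#'
#' Partitions patients (never individual records) into training and test
#' sets, so all series and windowing records of one patient land in the same
#' set. The split is over patients at the requested fraction; the achieved
#' record-level fraction is reported as an attribute because patients carry
#' different record counts.
#'
#' @param patient_ids character vector of patient identifiers (duplicates
#'   allowed; e.g. the \code{patient_id} column of a record table).
#' @param train_fraction fraction of patients assigned to training,
#'   strictly between 0 and 1. Default 0.7 (a 7:3 split).
#' @param seed integer seed; the split is deterministic given it.
#' @return named character vector over unique patients with values
#'   \code{"train"} / \code{"test"}; attribute \code{record_fraction} gives
#'   the achieved fraction of input rows in training.
#' @export
split_by_patient <- function(patient_ids, train_fraction = 0.7, seed = 1L) {
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("train_fraction must be strictly between 0 and 1")
  patients <- unique(as.character(patient_ids))
  if (length(patients) < 2L)
    stop("need at least 2 patients to split")
  n_train <- max(1L, min(length(patients) - 1L,
                         round(train_fraction * length(patients))))
  with_seed(seed, {
    train <- sample(patients, n_train)
  })
  split <- ifelse(patients %in% train, "train", "test")
  names(split) <- patients
  attr(split, "record_fraction") <-
    mean(split[as.character(patient_ids)] == "train")
  split
}

# Evaluate expr under a temporary RNG state so callers' streams are untouched.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
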