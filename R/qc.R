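#' Quality-control flags for one processed trial
#'
#' Applies the trial-rejection rules: a trial is invalid if the
#' participant's match/mismatch response was wrong (linguistic error),
#' if the movement was anticipated (reach onset before verb-stem onset,
#' i.e. before t = 0 on the trial clock, when the verb could not yet be
#' identified), or if the movement could not be segmented. Catch trials
#' are flagged separately and are never analyzed, whatever their
#' kinematics.
#'
#' @param kin_row A one-row data frame from [process_trial()].
#' @return A list of logicals: `linguistic_error`,
#'   `anticipated_movement`, `segmentation_failure`, `catch_trial`,
#'   `valid` (true iff no flag is set and the trial is not a catch
#'   trial).
#' @export
validate_trial <- function(kin_row) {
  stopifnot(is.data.frame(kin_row), nrow(kin_row) == 1L)
  seg_fail <- isTRUE(kin_row$segmentation_failure)
  antic <- !seg_fail && !is.na(kin_row$onset_ms) && kin_row$onset_ms < 0
  flags <- list(
    linguistic_error = isTRUE(kin_row$linguistic_error),
    anticipated_movement = antic,
    segmentation_failure = seg_fail,
    catch_trial = isTRUE(kin_row$is_catch)
  )
  flags$valid <- !any(unlist(flags))
  flags
}

#' Add quality-control flags to a per-trial parameter table
#'
#' Vectorized version of [validate_trial()]: appends the columns
#' `anticipated_movement` and `valid` (the `linguistic_error`,
#' `segmentation_failure` and `is_catch` columns are already present).
#'
#' @param params Data frame from [process_dataset()].
#' @return The table with QC columns appended.
#' @export
apply_qc <- function(params) {
  stopifnot(is.data.frame(params))
  seg <- isTRUE_vec(params$segmentation_failure)
  params$anticipated_movement <- !seg & !is.na(params$onset_ms) & params$onset_ms < 0
  params$valid <- !seg & !params$anticipated_movement &
    !isTRUE_vec(params$linguistic_error) & !isTRUE_vec(params$is_catch)
  params
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else !is.na(x) & x

#' Exclude participants with too few valid trials
#'
#' Removes subjects whose fraction of valid critical trials is below
#' `min_valid_fraction` (strictly below: a subject at exactly the
#' boundary is retained). Catch trials do not count toward the
#' denominator.
#'
#' @param params QC-flagged per-trial table (see [apply_qc()]).
#' @param min_valid_fraction Exclusion boundary, default 0.5.
#' @return A list with `params` (the filtered table) and `report` (one
#'   row per subject: `n_critical`, `n_valid`, `fraction`, `excluded`).
#' @export
filter_participants <- function(params, min_valid_fraction = 0.5) {
  stopifnot(is.data.frame(params))
  if (is.null(params$valid)) params <- apply_qc(params)
  crit <- !isTRUE_vec(params$is_catch)
  subjects <- unique(params$subject_id)
  n_critical <- vapply(subjects, function(s) sum(crit & params$subject_id == s), 0)
  n_valid <- vapply(subjects, function(s)
    sum(crit & params$subject_id == s & params$valid), 0)
  fraction <- ifelse(n_critical > 0, n_valid / n_critical, 0)
  excluded <- fraction < min_valid_fraction
  report <- data.frame(subject_id = subjects, n_critical = n_critical,
                       n_valid = n_valid, fraction = fraction,
                       excluded = excluded, row.names = NULL,
                       stringsAsFactors = FALSE)
  if (all(excluded)) {
    stop("all participants fall below the valid-trial criterion", call. = FALSE)
  }
  keep <- params$subject_id %in% subjects[!excluded]
  list(params = params[keep, , drop = FALSE], report = report)
}
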