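#' Extract kinematic parameters from one trial
#'
#' Runs the full signal chain on a single trial: zero-phase low-pass
#' filtering of the marker positions, tangential wrist speed, movement
#' segmentation according to the configured rule variant, and parameter
#' extraction. The displacement variant analyzes both components
#' (transport and grip: the grasp window is segmented first because its
#' end time arbitrates the reach end); the velocity variant analyzes the
#' transport component only, as in wrist-only recordings.
#'
#' A segmentation failure never raises an error: the affected parameters
#' are `NA` and the `segmentation_failure` flag is set, so the trial can
#' be rejected by the quality-control stage while the pipeline continues.
#'
#' @param trial A [trial_record()].
#' @param cfg A [segmentation_config()].
#' @return A one-row data frame of trial identifiers, condition labels,
#'   movement onset/offset (ms, trial clock), reach and grasp parameters
#'   and flags.
#' @export
process_trial <- function(trial, cfg = segmentation_config()) {
  if (!inherits(trial, "trial_record")) stop("`trial` must be a trial_record", call. = FALSE)
  wrist <- trial$markers$wrist
  if (is.null(wrist)) stop("trial has no wrist marker", call. = FALSE)
  rate <- sampling_rate(wrist)
  if (cfg$filter_cutoff_hz >= rate / 2) {
    stop("filter cutoff must be below the Nyquist frequency of the recording",
         call. = FALSE)
  }
  t_ms <- wrist$t_ms
  has_grip <- !is.null(trial$markers$index) && !is.null(trial$markers$thumb)

  # filter all needed series in one call: wrist axes, then (for the
  # grip component) the index-thumb difference vector, whose filtered
  # norm equals the filtered aperture because the filter is linear
  cols <- cbind(wrist$x_mm, wrist$y_mm, wrist$z_mm)
  if (has_grip) {
    ix <- trial$markers$index
    th <- trial$markers$thumb
    cols <- cbind(cols, ix$x_mm - th$x_mm, ix$y_mm - th$y_mm, ix$z_mm - th$z_mm)
  }
  f <- lowpass_mat(cols, rate, cfg$filter_cutoff_hz, cfg$filter_order)
  wristf <- structure(list(t_ms = t_ms, x_mm = f[, 1L], y_mm = f[, 2L],
                           z_mm = f[, 3L]), class = "trajectory")
  speed <- marker_speed(wristf)
  aperture <- if (has_grip) sqrt(f[, 4L]^2 + f[, 5L]^2 + f[, 6L]^2) else NULL

  grasp <- NULL
  reasons <- character(0)
  if (identical(cfg$variant, "displacement_exp1")) {
    gwin <- if (has_grip) segment_grasp(aperture, t_ms, cfg) else
      window_failure("no finger markers for the grip component")
    if (!gwin$ok) reasons <- c(reasons, gwin$reason)
    # failed grasp segmentation: fall back to the latest per-axis
    # candidate (grasp end at +Inf selects it) and flag the trial
    grasp_end <- if (gwin$ok) gwin$offset_ms else Inf
    rwin <- segment_reach_displacement(wristf, grasp_end, cfg)
    grasp <- extract_grasp_params(aperture, t_ms, gwin)
    grasp_onset <- if (gwin$ok) gwin$onset_ms else NA_real_
    grasp_failed <- !gwin$ok
  } else {
    rwin <- segment_reach_velocity(speed, t_ms, cfg)
    grasp <- list(grasp_time_ms = NA_real_, max_aperture_mm = NA_real_,
                  t_max_aperture_ms = NA_real_, pct_t_max_aperture = NA_real_,
                  degenerate_peak = FALSE)
    grasp_onset <- NA_real_
    grasp_failed <- FALSE
  }
  if (!rwin$ok) reasons <- c(reasons, rwin$reason)
  reach <- extract_reach_params(speed, t_ms, rwin)
  if (isTRUE(reach$degenerate_peak)) reasons <- c(reasons, "velocity peak on window boundary")

  data.frame(
    subject_id = trial$subject_id,
    trial_id = trial$trial_id,
    pronoun = trial$condition$pronoun,
    verb_type = trial$condition$verb_type,
    verb = trial$condition$verb,
    is_catch = trial$condition$is_catch,
    linguistic_error = trial$linguistic_error,
    onset_ms = if (rwin$ok) rwin$onset_ms else NA_real_,
    offset_ms = if (rwin$ok) rwin$offset_ms else NA_real_,
    reach_time_ms = reach$reach_time_ms,
    vpeak_mm_s = reach$vpeak_mm_s,
    t_vpeak_ms = reach$t_vpeak_ms,
    pct_t_vpeak = reach$pct_t_vpeak,
    grasp_onset_ms = grasp_onset,
    grasp_time_ms = grasp$grasp_time_ms,
    max_aperture_mm = grasp$max_aperture_mm,
    t_max_aperture_ms = grasp$t_max_aperture_ms,
    pct_t_max_aperture = grasp$pct_t_max_aperture,
    segmentation_failure = !rwin$ok || isTRUE(reach$degenerate_peak) ||
      (identical(cfg$variant, "displacement_exp1") && grasp_failed),
    seg_reason = if (length(reasons)) paste(reasons, collapse = "; ") else NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Extract kinematic parameters from every trial of a dataset
#'
#' @param dataset A `trial_dataset` (from [simulate_experiment()] or
#'   [read_dataset()]).
#' @param cfg A [segmentation_config()]; by default the variant matching
#'   the dataset's sampling rate (displacement rule below 120 Hz,
#'   velocity rule above).
#' @return A data frame with one row per trial (see [process_trial()]).
#' @export
process_dataset <- function(dataset, cfg = NULL) {
  stopifnot(inherits(dataset, "trial_dataset"))
  if (!length(dataset$trials)) stop("dataset contains no trials", call. = FALSE)
  if (is.null(cfg)) {
    rate <- sampling_rate(dataset$trials[[1L]]$markers$wrist)
    cfg <- segmentation_config(default_variant(rate))
  }
  rows <- lapply(dataset$trials, process_trial, cfg = cfg)
  out <- data.table::rbindlist(rows)
  data.table::setDF(out)
  out
}
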