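#' Movement segmentation settings
#'
#' Thresholds and filter settings for movement onset/offset detection.
#' Two rule variants are supported:
#'
#' * `displacement_exp1` (60 Hz optical recordings): the reach begins at
#'   the first frame whose wrist displacement exceeds
#'   `displacement_threshold_mm` on all three Cartesian axes; the reach
#'   ends, among the three per-axis candidates (first frame after the
#'   velocity peak with per-axis displacement below the threshold), at
#'   the one closest in time to the grasp end.
#' * `velocity_exp2` (200 Hz electromagnetic recordings): the reach
#'   begins and ends at the first and last frame with wrist speed above
#'   `velocity_threshold_mm_s`.
#'
#' "Displacement" is read as frame-to-frame displacement by default
#' (`displacement_mode = "frame"`); the cumulative-from-rest reading is
#' available as `displacement_mode = "cumulative"` for the onset rule.
#'
#' @param variant `"displacement_exp1"` or `"velocity_exp2"`.
#' @param displacement_threshold_mm Displacement threshold (mm),
#'   default 0.3 (the spatial resolution of the optical system).
#' @param velocity_threshold_mm_s Speed threshold (mm/s), default 1.
#' @param filter_cutoff_hz,filter_order Low-pass settings applied to the
#'   raw positions before any differentiation or thresholding.
#' @param displacement_mode `"frame"` or `"cumulative"`.
#' @param grasp_offset_mode `"baseline"` (default): the grasp ends at
#'   the first frame after the aperture maximum in which the aperture
#'   has closed back to within the displacement threshold of its
#'   initial value, mirroring the onset rule. `"step"`: first frame
#'   after the maximum whose frame-to-frame aperture change is below
#'   the threshold -- degenerate on smooth data, where the slope
#'   vanishes at the maximum itself, but retained as the literal
#'   frame-displacement reading.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(variant = c("displacement_exp1", "velocity_exp2"),
                                displacement_threshold_mm = 0.3,
                                velocity_threshold_mm_s = 1,
                                filter_cutoff_hz = 10,
                                filter_order = 2,
                                displacement_mode = c("frame", "cumulative"),
                                grasp_offset_mode = c("baseline", "step")) {
  variant <- match.arg(variant)
  displacement_mode <- match.arg(displacement_mode)
  grasp_offset_mode <- match.arg(grasp_offset_mode)
  check_positive(displacement_threshold_mm, "displacement_threshold_mm")
  check_positive(velocity_threshold_mm_s, "velocity_threshold_mm_s")
  check_positive(filter_cutoff_hz, "filter_cutoff_hz")
  structure(list(variant = variant,
                 displacement_threshold_mm = displacement_threshold_mm,
                 velocity_threshold_mm_s = velocity_threshold_mm_s,
                 filter_cutoff_hz = filter_cutoff_hz,
                 filter_order = as.integer(filter_order),
                 displacement_mode = displacement_mode,
                 grasp_offset_mode = grasp_offset_mode),
            class = "segmentation_config")
}

# Default variant for a sampling rate: optical 60 Hz recordings use the
# displacement rule, 200 Hz electromagnetic recordings the velocity rule.
default_variant <- function(rate_hz) {
  if (rate_hz >= 120) "velocity_exp2" else "displacement_exp1"
}

movement_window <- function(onset_idx = NA_integer_, offset_idx = NA_integer_,
                            t_ms = NULL, ok = TRUE, reason = NA_character_) {
  structure(list(
    onset_idx = onset_idx, offset_idx = offset_idx,
    onset_ms = if (ok) t_ms[onset_idx] else NA_real_,
    offset_ms = if (ok) t_ms[offset_idx] else NA_real_,
    ok = ok, reason = reason
  ), class = "movement_window")
}

window_failure <- function(reason) movement_window(ok = FALSE, reason = reason)

#' @export
print.movement_window <- function(x, ...) {
  if (x$ok) {
    cat(sprintf("<movement_window> [%.1f, %.1f] ms (%.1f ms)\n",
                x$onset_ms, x$offset_ms, x$offset_ms - x$onset_ms))
  } else {
    cat(sprintf("<movement_window> segmentation failure: %s\n", x$reason))
  }
  invisible(x)
}

#' Reach segmentation by per-axis displacement thresholds
#'
#' Implements the displacement rule for 60 Hz optical recordings:
#' the reach onset is the first frame whose wrist displacement exceeds
#' the threshold simultaneously on all three Cartesian axes; for the
#' reach end, each axis proposes the first frame after the velocity peak
#' with per-axis displacement below the threshold, and the candidate
#' closest in time to `grasp_end_ms` is selected (ties go to the earlier
#' frame). Failure to find an onset or any offset candidate yields a
#' flagged (not thrown) segmentation failure, so the trial can be
#' rejected downstream.
#'
#' @param wrist A (filtered) wrist [trajectory()].
#' @param grasp_end_ms Grasp end time used to arbitrate between the
#'   per-axis offset candidates.
#' @param cfg A [segmentation_config()].
#' @return A `movement_window`.
#' @export
segment_reach_displacement <- function(wrist, grasp_end_ms, cfg = segmentation_config()) {
  wrist <- as_trajectory(wrist)
  t_ms <- wrist$t_ms
  xyz <- cbind(wrist$x_mm, wrist$y_mm, wrist$z_mm)
  n <- nrow(xyz)
  thr <- cfg$displacement_threshold_mm
  step <- abs(xyz[-1L, , drop = FALSE] - xyz[-n, , drop = FALSE])
  # onset: displacement beyond threshold on all three axes at once;
  # row k of `step` is the displacement arriving at frame k + 1
  onset_disp <- if (identical(cfg$displacement_mode, "cumulative")) {
    abs(xyz[-1L, , drop = FALSE] -
          matrix(xyz[1L, ], n - 1L, 3L, byrow = TRUE))
  } else {
    step
  }
  over <- rowSums(onset_disp > thr) == 3L
  if (!any(over)) return(window_failure("no onset frame crosses the displacement threshold"))
  onset_idx <- which(over)[1L] + 1L
  v <- marker_speed(wrist)
  peak_idx <- which.max(v)
  if (peak_idx <= 1L || peak_idx >= n) {
    return(window_failure("velocity peak lies on the trajectory boundary"))
  }
  # per-axis offset candidates after the velocity peak
  cand_idx <- rep(NA_integer_, 3L)
  for (ax in 1:3) {
    rows <- which(step[, ax] < thr)
    rows <- rows[rows + 1L > peak_idx]
    if (length(rows)) cand_idx[ax] <- rows[1L] + 1L
  }
  if (all(is.na(cand_idx))) {
    return(window_failure("no axis settles below the displacement threshold after the peak"))
  }
  cand_t <- t_ms[cand_idx]
  dist <- abs(cand_t - grasp_end_ms)
  offset_idx <- cand_idx[order(dist, cand_t)][1L]
  if (is.na(offset_idx) || offset_idx <= onset_idx) {
    return(window_failure("reach offset does not follow the onset"))
  }
  movement_window(onset_idx, offset_idx, t_ms)
}

#' Reach segmentation by a speed threshold
#'
#' Implements the velocity rule for 200 Hz recordings: the reach spans
#' the first through the last frame in which the wrist speed exceeds the
#' threshold (1 mm/s by default).
#'
#' @param speed Numeric vector of wrist speeds (mm/s).
#' @param t_ms Frame times (ms) matching `speed`.
#' @param cfg A [segmentation_config()].
#' @return A `movement_window`.
#' @export
segment_reach_velocity <- function(speed, t_ms, cfg = segmentation_config("velocity_exp2")) {
  stopifnot(length(speed) == length(t_ms))
  over <- which(speed > cfg$velocity_threshold_mm_s)
  if (!length(over)) {
    return(window_failure("speed never exceeds the velocity threshold"))
  }
  onset_idx <- over[1L]
  offset_idx <- over[length(over)]
  if (offset_idx <= onset_idx) {
    return(window_failure("speed exceeds the threshold on a single frame"))
  }
  movement_window(onset_idx, offset_idx, t_ms)
}

#' Grasp segmentation from the aperture series
#'
#' The grasp begins at the first frame in which the aperture has moved
#' more than the displacement threshold away from its initial (resting)
#' value, and ends -- after the aperture maximum -- according to
#' `cfg$grasp_offset_mode` (see [segmentation_config()]): by default at
#' the first frame in which the aperture has closed back to within the
#' threshold of its initial value. Physical finger markers never reach
#' an absolute separation below the threshold, so both rules are
#' measured as change relative to the resting aperture.
#'
#' @param aperture Numeric vector of index-thumb distances (mm).
#' @param t_ms Frame times (ms) matching `aperture`.
#' @param cfg A [segmentation_config()].
#' @return A `movement_window`.
#' @export
segment_grasp <- function(aperture, t_ms, cfg = segmentation_config()) {
  stopifnot(length(aperture) == length(t_ms))
  n <- length(aperture)
  thr <- cfg$displacement_threshold_mm
  over <- which(abs(aperture - aperture[1L]) > thr)
  if (!length(over)) {
    return(window_failure("aperture never departs from its baseline"))
  }
  onset_idx <- over[1L]
  max_idx <- which.max(aperture)
  if (max_idx <= 1L || max_idx >= n) {
    return(window_failure("aperture maximum lies on the series boundary"))
  }
  if (identical(cfg$grasp_offset_mode, "step")) {
    step <- abs(diff(aperture))
    rows <- which(step < thr)
    rows <- rows[rows + 1L > max_idx]
    if (!length(rows)) {
      return(window_failure("aperture never settles after its maximum"))
    }
    offset_idx <- rows[1L] + 1L
  } else {
    rows <- which(abs(aperture - aperture[1L]) < thr)
    rows <- rows[rows > max_idx]
    if (!length(rows)) {
      return(window_failure("aperture never returns to baseline after its maximum"))
    }
    offset_idx <- rows[1L]
  }
  if (offset_idx <= onset_idx) {
    return(window_failure("grasp offset does not follow the onset"))
  }
  movement_window(onset_idx, offset_idx, t_ms)
}

#' Reach parameters within a movement window
#'
#' Computes the transport-component dependent variables: reach time,
#' velocity-peak amplitude, velocity-peak latency from reach onset, and
#' the normalized latency (% of reach time). The peak is the first
#' maximal speed sample inside the window; no sub-frame interpolation is
#' performed, since published movement times are frame-quantized.
#'
#' @param speed Numeric vector of wrist speeds (mm/s).
#' @param t_ms Frame times (ms) matching `speed`.
#' @param window A `movement_window` from one of the reach segmenters.
#' @return A list with `reach_time_ms`, `vpeak_mm_s`, `t_vpeak_ms`,
#'   `pct_t_vpeak`, and a `degenerate_peak` flag (peak on the window
#'   boundary).
#' @export
extract_reach_params <- function(speed, t_ms, window) {
  empty <- list(reach_time_ms = NA_real_, vpeak_mm_s = NA_real_,
                t_vpeak_ms = NA_real_, pct_t_vpeak = NA_real_,
                degenerate_peak = FALSE)
  if (!window$ok) return(empty)
  idx <- window$onset_idx:window$offset_idx
  vs <- speed[idx]
  pk <- idx[which.max(vs)]
  reach_time <- window$offset_ms - window$onset_ms
  out <- list(reach_time_ms = reach_time,
              vpeak_mm_s = speed[pk],
              t_vpeak_ms = t_ms[pk] - window$onset_ms,
              pct_t_vpeak = 100 * (t_ms[pk] - window$onset_ms) / reach_time,
              degenerate_peak = pk == window$onset_idx || pk == window$offset_idx)
  out
}

#' Grasp parameters within a movement window
#'
#' Computes the grip-component dependent variables: grasp time, maximal
#' finger aperture, its latency from grasp onset, and the normalized
#' latency (% of grasp time). Analogous to [extract_reach_params()]
#' with the aperture maximum in place of the velocity peak.
#'
#' @param aperture Numeric vector of index-thumb distances (mm).
#' @param t_ms Frame times (ms) matching `aperture`.
#' @param window A `movement_window` from [segment_grasp()].
#' @return A list with `grasp_time_ms`, `max_aperture_mm`,
#'   `t_max_aperture_ms`, `pct_t_max_aperture` and a `degenerate_peak`
#'   flag.
#' @export
extract_grasp_params <- function(aperture, t_ms, window) {
  empty <- list(grasp_time_ms = NA_real_, max_aperture_mm = NA_real_,
                t_max_aperture_ms = NA_real_, pct_t_max_aperture = NA_real_,
                degenerate_peak = FALSE)
  if (!window$ok) return(empty)
  idx <- window$onset_idx:window$offset_idx
  ap <- aperture[idx]
  pk <- idx[which.max(ap)]
  grasp_time <- window$offset_ms - window$onset_ms
  list(grasp_time_ms = grasp_time,
       max_aperture_mm = aperture[pk],
       t_max_aperture_ms = t_ms[pk] - window$onset_ms,
       pct_t_max_aperture = 100 * (t_ms[pk] - window$onset_ms) / grasp_time,
       degenerate_peak = pk == window$onset_idx || pk == window$offset_idx)
}
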