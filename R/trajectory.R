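#' Marker trajectory
#'
#' A time-stamped 3-D position series for a single marker. Times are in
#' milliseconds on the trial clock (0 = onset of the verb stem, the
#' earliest moment a response is legitimate), positions in millimetres.
#' Sampling must be uniform.
#'
#' @param t_ms Strictly increasing numeric vector of frame times (ms).
#' @param x_mm,y_mm,z_mm Numeric vectors of positions (mm), same length
#'   as `t_ms`.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(t_ms, x_mm, y_mm, z_mm) {
  obj <- structure(
    list(t_ms = as.numeric(t_ms), x_mm = as.numeric(x_mm),
         y_mm = as.numeric(y_mm), z_mm = as.numeric(z_mm)),
    class = "trajectory"
  )
  validate_trajectory(obj)
}

validate_trajectory <- function(traj) {
  n <- length(traj$t_ms)
  if (n < 2L) stop("a trajectory needs at least 2 frames", call. = FALSE)
  lens <- lengths(traj[c("x_mm", "y_mm", "z_mm")])
  if (any(lens != n)) {
    stop("trajectory axis vectors must match the length of `t_ms`", call. = FALSE)
  }
  dt <- diff(traj$t_ms)
  if (any(dt <= 0)) stop("`t_ms` must be strictly increasing", call. = FALSE)
  # uniform sampling to 1 microsecond
  if (max(dt) - min(dt) > 1e-3) {
    stop("trajectory sampling interval is not uniform", call. = FALSE)
  }
  traj
}

as_trajectory <- function(x) {
  if (inherits(x, "trajectory")) return(x)
  if (is.list(x) && all(c("t_ms", "x_mm", "y_mm", "z_mm") %in% names(x))) {
    return(structure(list(t_ms = as.numeric(x$t_ms), x_mm = as.numeric(x$x_mm),
                          y_mm = as.numeric(x$y_mm), z_mm = as.numeric(x$z_mm)),
                     class = "trajectory"))
  }
  stop("cannot interpret object as a trajectory", call. = FALSE)
}

#' @export
print.trajectory <- function(x, ...) {
  dt <- diff(x$t_ms[1:2])
  cat(sprintf("<trajectory> %d frames @ %.4g Hz, t = [%.1f, %.1f] ms\n",
              length(x$t_ms), 1000 / dt, x$t_ms[1], x$t_ms[length(x$t_ms)]))
  invisible(x)
}

sampling_rate <- function(traj) 1000 / (traj$t_ms[2] - traj$t_ms[1])

#' Stimulus timeline of one trial
#'
#' Durations of the visual events preceding and accompanying the
#' movement: fixation cross, pronoun, verb stem, verb suffix. The trial
#' clock is anchored at verb-stem onset (t = 0), because participants
#' may start moving only once the verb is identifiable; a movement onset
#' at t < 0 is an anticipation.
#'
#' @param fixation_ms,pronoun_ms,stem_ms,suffix_ms Durations in ms.
#' @return An object of class `stimulus_timeline`.
#' @export
stimulus_timeline <- function(fixation_ms = 1000, pronoun_ms = 500,
                              stem_ms = 500, suffix_ms = 500) {
  vals <- c(fixation_ms = fixation_ms, pronoun_ms = pronoun_ms,
            stem_ms = stem_ms, suffix_ms = suffix_ms)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all stimulus durations must be positive", call. = FALSE)
  }
  structure(as.list(vals), class = "stimulus_timeline")
}

#' Trial condition
#'
#' The experimental cell of a trial: grammatical person of the pronoun
#' (I, YOU, HE), verb category (AV = action verb, e.g. "to grasp";
#' IV = interaction verb, e.g. "to give"), the verb label itself, and
#' whether the trial is a catch trial (person-mismatched pronoun-verb
#' pair, to be withheld and excluded from analysis).
#'
#' @param pronoun One of `"I"`, `"YOU"`, `"HE"`.
#' @param verb_type One of `"AV"`, `"IV"`.
#' @param verb Free-text verb label.
#' @param is_catch Logical flag for catch trials.
#' @return An object of class `condition`.
#' @export
condition <- function(pronoun, verb_type, verb = "", is_catch = FALSE) {
  pronoun <- match.arg(pronoun, PRONOUNS)
  verb_type <- match.arg(verb_type, VERB_TYPES)
  structure(list(pronoun = pronoun, verb_type = verb_type,
                 verb = as.character(verb), is_catch = isTRUE(is_catch)),
            class = "condition")
}

PRONOUNS <- c("I", "YOU", "HE")
VERB_TYPES <- c("AV", "IV")

cell_key <- function(pronoun, verb_type) paste(pronoun, verb_type, sep = ".")

#' Single-trial record
#'
#' Bundles the three marker trajectories of one reach-to-grasp trial
#' with its identifiers, condition and stimulus timeline. The wrist
#' marker is mandatory (velocity-threshold analyses use only it); index
#' and thumb are needed for the grip component.
#'
#' @param subject_id,trial_id Identifiers (coerced to character).
#' @param condition A [condition()] object.
#' @param markers Named list with elements `wrist`, and optionally
#'   `index` and `thumb`, each a [trajectory()]; all on the same time grid.
#' @param timeline A [stimulus_timeline()].
#' @param linguistic_error Logical; whether the participant's
#'   match/mismatch response was wrong (planted by the generator, not
#'   recoverable from kinematics).
#' @return An object of class `trial_record`.
#' @export
trial_record <- function(subject_id, trial_id, condition, markers,
                         timeline = stimulus_timeline(),
                         linguistic_error = FALSE) {
  if (!inherits(condition, "condition")) stop("`condition` must be a condition object", call. = FALSE)
  if (!is.list(markers) || is.null(markers$wrist)) {
    stop("`markers` must contain at least a `wrist` trajectory", call. = FALSE)
  }
  markers <- lapply(markers, as_trajectory)
  t0 <- markers$wrist$t_ms
  for (m in names(markers)) {
    if (length(markers[[m]]$t_ms) != length(t0) ||
        max(abs(markers[[m]]$t_ms - t0)) > 1e-6) {
      stop("all markers must share one time grid", call. = FALSE)
    }
  }
  structure(list(subject_id = as.character(subject_id),
                 trial_id = as.character(trial_id),
                 condition = condition, timeline = timeline,
                 markers = markers,
                 linguistic_error = isTRUE(linguistic_error)),
            class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record> subject %s trial %s: %s/%s%s, markers: %s\n",
              x$subject_id, x$trial_id, x$condition$pronoun,
              x$condition$verb_type,
              if (x$condition$is_catch) " (catch)" else "",
              paste(names(x$markers), collapse = ", ")))
  invisible(x)
}

new_trial_dataset <- function(trials, config = NULL) {
  structure(list(trials = trials, config = config), class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  n <- length(x$trials)
  subj <- unique(vapply(x$trials, function(tr) tr$subject_id, character(1)))
  cat(sprintf("<trial_dataset> %d trials, %d subjects\n", n, length(subj)))
  invisible(x)
}

#' @export
length.trial_dataset <- function(x) length(x$trials)
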