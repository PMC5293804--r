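#' Configuration of the synthetic trial generator
#'
#' Collects everything the generator needs to simulate a within-subject
#' 2 (verb type) x 3 (pronoun) reach-to-grasp experiment: sampling rate,
#' reach amplitude, design size, per-cell true parameter means,
#' between-subject and trial-to-trial variability, measurement noise and
#' the reaction-time offset separating verb-stem onset from movement
#' onset.
#'
#' Two presets calibrated to published condition means are available via
#' [generator_preset()]. Variability defaults describe, per kinematic
#' parameter, the standard deviation of a subject-level random offset
#' (shared by all of a subject's trials) and of an independent
#' trial-level deviation. The grasp window tracks the reach window: its
#' subject- and trial-level deviations are tied to the reach-time
#' deviations, reflecting that transport and grip are two components of
#' one movement.
#'
#' @param sampling_rate_hz Sampling rate, 60 or 200 Hz in the presets
#'   (any positive rate is accepted).
#' @param reach_amplitude_mm Path length of the reach in mm.
#' @param n_subjects,n_trials_per_condition Design size.
#' @param catch_fraction Fraction of all trials that are catch trials,
#'   in [0, 1).
#' @param condition_means Data frame with columns `pronoun`,
#'   `verb_type`, `reach_time_ms`, `pct_t_vpeak`, `grasp_time_ms`,
#'   `max_aperture_mm`; all six (pronoun, verb type) cells required.
#' @param between_subject_sd Named list of subject-level offset SDs for
#'   `reach_time_ms`, `pct_t_vpeak`, `max_aperture_mm`.
#' @param trial_sd Named list of trial-level SDs for the same parameters.
#' @param trial_noise_sd_mm Isotropic Gaussian position noise SD (mm)
#'   added to every marker sample.
#' @param rt_mean_ms,rt_sd_ms Mean and SD of the reaction time from
#'   verb-stem onset to movement onset.
#' @param linguistic_error_rate Probability that a trial carries a wrong
#'   match/mismatch response and is flagged for rejection.
#' @param baseline_aperture_mm Resting index-thumb distance (mm).
#' @param aperture_peak_fraction Location of the aperture maximum as a
#'   fraction of the grasp duration.
#' @param record_pre_ms,record_post_ms Recorded margin before verb-stem
#'   onset and after movement end.
#' @param seed Default seed used when none is passed to the simulators.
#' @return An object of class `generator_config`.
#' @seealso [generator_preset()], [simulate_experiment()]
#' @export
generator_config <- function(sampling_rate_hz = 60,
                             reach_amplitude_mm = 330,
                             n_subjects = 12,
                             n_trials_per_condition = 5,
                             catch_fraction = 0.25,
                             condition_means = default_condition_means(),
                             between_subject_sd = list(reach_time_ms = 40,
                                                       pct_t_vpeak = 1.5,
                                                       max_aperture_mm = 3),
                             trial_sd = list(reach_time_ms = 30,
                                             pct_t_vpeak = 2,
                                             max_aperture_mm = 2),
                             trial_noise_sd_mm = 0.05,
                             rt_mean_ms = 250,
                             rt_sd_ms = 50,
                             linguistic_error_rate = 0.015,
                             baseline_aperture_mm = 5,
                             aperture_peak_fraction = 0.66,
                             record_pre_ms = 100,
                             record_post_ms = 100,
                             seed = 1L) {
  cfg <- structure(list(
    sampling_rate_hz = sampling_rate_hz,
    reach_amplitude_mm = reach_amplitude_mm,
    n_subjects = as.integer(n_subjects),
    n_trials_per_condition = as.integer(n_trials_per_condition),
    catch_fraction = catch_fraction,
    condition_means = as.data.frame(condition_means),
    between_subject_sd = between_subject_sd,
    trial_sd = trial_sd,
    trial_noise_sd_mm = trial_noise_sd_mm,
    rt_mean_ms = rt_mean_ms,
    rt_sd_ms = rt_sd_ms,
    linguistic_error_rate = linguistic_error_rate,
    baseline_aperture_mm = baseline_aperture_mm,
    aperture_peak_fraction = aperture_peak_fraction,
    record_pre_ms = record_pre_ms,
    record_post_ms = record_post_ms,
    seed = as.integer(seed)
  ), class = "generator_config")
  validate_generator_config(cfg)
}

PARAM_NAMES <- c("reach_time_ms", "pct_t_vpeak", "grasp_time_ms", "max_aperture_mm")

validate_generator_config <- function(cfg) {
  check_positive(cfg$sampling_rate_hz, "sampling_rate_hz")
  check_positive(cfg$reach_amplitude_mm, "reach_amplitude_mm")
  if (cfg$n_subjects < 1L) stop("`n_subjects` must be positive", call. = FALSE)
  if (cfg$n_trials_per_condition < 1L) {
    stop("`n_trials_per_condition` must be positive", call. = FALSE)
  }
  if (!is.numeric(cfg$catch_fraction) || cfg$catch_fraction < 0 ||
      cfg$catch_fraction >= 1) {
    stop("`catch_fraction` must lie in [0, 1)", call. = FALSE)
  }
  cm <- cfg$condition_means
  needed <- c("pronoun", "verb_type", PARAM_NAMES)
  missing_cols <- setdiff(needed, names(cm))
  if (length(missing_cols)) {
    stop("`condition_means` lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  cells <- cell_key(cm$pronoun, cm$verb_type)
  wanted <- cell_key(rep(PRONOUNS, each = 2), rep(VERB_TYPES, 3))
  if (!setequal(cells, wanted) || anyDuplicated(cells)) {
    stop("`condition_means` must contain each of the six pronoun x verb cells once",
         call. = FALSE)
  }
  if (any(cm$pct_t_vpeak <= 0 | cm$pct_t_vpeak >= 100)) {
    stop("`pct_t_vpeak` means must lie strictly in (0, 100)", call. = FALSE)
  }
  if (any(cm$reach_time_ms <= 0 | cm$grasp_time_ms <= 0)) {
    stop("reach and grasp time means must be positive", call. = FALSE)
  }
  if (any(cm$max_aperture_mm <= cfg$baseline_aperture_mm)) {
    stop("`max_aperture_mm` means must exceed the aperture baseline", call. = FALSE)
  }
  for (f in c("between_subject_sd", "trial_sd")) {
    sds <- cfg[[f]]
    if (!all(c("reach_time_ms", "pct_t_vpeak", "max_aperture_mm") %in% names(sds))) {
      stop("`", f, "` must name reach_time_ms, pct_t_vpeak and max_aperture_mm",
           call. = FALSE)
    }
    if (any(unlist(sds) < 0)) stop("`", f, "` entries must be non-negative", call. = FALSE)
  }
  if (cfg$trial_noise_sd_mm < 0) stop("`trial_noise_sd_mm` must be non-negative", call. = FALSE)
  if (cfg$rt_sd_ms < 0) stop("`rt_sd_ms` must be non-negative", call. = FALSE)
  if (cfg$linguistic_error_rate < 0 || cfg$linguistic_error_rate >= 1) {
    stop("`linguistic_error_rate` must lie in [0, 1)", call. = FALSE)
  }
  check_peak_fraction(cfg$aperture_peak_fraction)
  cfg
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(paste0("<generator_config> %g Hz, %g mm reach, %d subjects x ",
                     "%d trials/cell, catch fraction %.2f\n"),
              x$sampling_rate_hz, x$reach_amplitude_mm, x$n_subjects,
              x$n_trials_per_condition, x$catch_fraction))
  print(x$condition_means, row.names = FALSE)
  invisible(x)
}

# Default calibration: the Italian 60 Hz experiment (see generator_preset).
default_condition_means <- function() exp1_condition_means()

exp1_condition_means <- function() {
  reach <- c(742.6, 685.6, 744.8, 705.1, 729.8, 720.7)
  pct <- c(49.4, 52.2, 48.5, 51.8, 47.4, 49.3)
  data.frame(
    pronoun = rep(PRONOUNS, 2),
    verb_type = rep(VERB_TYPES, each = 3),
    reach_time_ms = reach,
    pct_t_vpeak = pct,
    grasp_time_ms = reach,
    max_aperture_mm = 85
  )
}

exp2_condition_means <- function() {
  reach <- c(883.4, 869.3, 868.5, 861.2, 879.8, 894.5)
  pct <- c(31.6, 31.7, 32.3, 31.6, 31.0, 31.2)
  data.frame(
    pronoun = rep(PRONOUNS, 2),
    verb_type = rep(VERB_TYPES, each = 3),
    reach_time_ms = reach,
    pct_t_vpeak = pct,
    grasp_time_ms = reach,
    max_aperture_mm = 85
  )
}

#' Generator presets for the two study designs
#'
#' `exp1_italian`: 60 Hz optical capture, 330 mm reach, 12 subjects,
#' 5 critical trials per cell plus 10 catch trials (one block of 40).
#' `exp2_german`: 200 Hz electromagnetic capture, 350 mm reach, 13
#' subjects, 14 critical trials per cell plus 16 catch trials (one block
#' of 100). Cell means of reach time and normalized velocity-peak
#' latency are the published condition means of each design; grip
#' parameters (aperture baseline and maximum, aperture peak latency) are
#' conventional values, since no aperture magnitudes are published.
#'
#' @param name `"exp1_italian"` or `"exp2_german"`.
#' @param ... Overrides passed on to [generator_config()].
#' @return A [generator_config()].
#' @examples
#' cfg <- generator_preset("exp1_italian", n_subjects = 2)
#' @export
generator_preset <- function(name = c("exp1_italian", "exp2_german"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    exp1_italian = list(sampling_rate_hz = 60, reach_amplitude_mm = 330,
                        n_subjects = 12, n_trials_per_condition = 5,
                        catch_fraction = 0.25,
                        condition_means = exp1_condition_means()),
    exp2_german = list(sampling_rate_hz = 200, reach_amplitude_mm = 350,
                       n_subjects = 13, n_trials_per_condition = 14,
                       catch_fraction = 0.16,
                       condition_means = exp2_condition_means(),
                       # electromagnetic tracking resolves well below the
                       # 1 mm/s velocity threshold; keep its noise floor low
                       trial_noise_sd_mm = 0.01)
  )
  over <- list(...)
  base[names(over)] <- over
  do.call(generator_config, base)
}

#' Strip all randomness from a generator configuration
#'
#' Returns a copy with zero between-subject offsets, zero trial-level
#' parameter deviations, zero position noise, zero reaction-time spread
#' and no planted linguistic errors, so every trial realizes its cell's
#' true means. Used for round-trip checks of the extraction pipeline.
#'
#' @param config A [generator_config()].
#' @return A [generator_config()] with all noise sources zeroed.
#' @export
noiseless <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  config$between_subject_sd <- lapply(config$between_subject_sd, function(x) 0)
  config$trial_sd <- lapply(config$trial_sd, function(x) 0)
  config$trial_noise_sd_mm <- 0
  config$rt_sd_ms <- 0
  config$linguistic_error_rate <- 0
  config
}

#' Stimulus verbs of the two designs
#'
#' The verb labels (infinitive, category, the three pronoun-inflected
#' forms, language and English gloss) used to label simulated trials.
#'
#' @param experiment `"exp1"`, `"exp2"` or `"all"`.
#' @return A data frame of verb labels.
#' @export
stimulus_verbs <- function(experiment = c("all", "exp1", "exp2")) {
  experiment <- match.arg(experiment)
  path <- system.file("extdata", "stimulus_verbs.tsv", package = "reachgrasp",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (experiment != "all") tab <- tab[tab$experiment == experiment, ]
  tab
}
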