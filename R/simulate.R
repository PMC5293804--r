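## Synthetic reach-to-grasp trial generator.
##
## Geometry: the wrist travels along a fixed transport direction with
## small lift components on the two other axes (so per-axis displacement
## thresholds are all exercised); index and thumb sit at plus/minus half
## the aperture along a fixed grip axis orthogonal to the transport
## direction, so the inter-marker distance equals the aperture profile
## by construction.

TRANSPORT_AXIS <- {
  u <- c(0.20, 1.00, 0.30)
  u / sqrt(sum(u^2))
}
GRIP_AXIS <- {
  u <- TRANSPORT_AXIS
  g <- c(u[2], -u[1], 0)
  g / sqrt(sum(g^2))
}

# Deterministic per-subject / per-trial seed stream: every random draw
# of a simulated experiment flows from one master seed through this
# counter-based scrambling, so any single trial is reproducible in
# isolation.
stream_seed <- function(seed, subject = 0L, counter = 0L) {
  as.integer((abs(seed) %% 1000003) * 1009 + subject * 7919 + counter * 104729) %% 2147483629L
}

# ---------------------------------------------------------------------------
# trial construction

# Noiseless trial geometry for given *underlying* profile parameters.
# `under` has T_u (reach duration ms), pf_u (speed peak fraction),
# Tg_u (grasp duration ms), ap (max aperture mm).
build_trial_arrays <- function(under, rt_ms, config) {
  rate <- config$sampling_rate_hz
  dt <- 1000 / rate
  t_end <- rt_ms + max(under$T_u, under$Tg_u) + config$record_post_ms
  t_ms <- seq(-config$record_pre_ms, by = dt,
              length.out = ceiling((t_end + config$record_pre_ms) / dt) + 1L)
  tau <- pmin(pmax((t_ms - rt_ms) / under$T_u, 0), 1)
  s <- beta_path(tau, under$pf_u, config$reach_amplitude_mm)
  wrist <- outer(s, TRANSPORT_AXIS)
  taug <- pmin(pmax((t_ms - rt_ms) / under$Tg_u, 0), 1)
  ap <- aperture_bump(taug, config$baseline_aperture_mm, under$ap,
                      config$aperture_peak_fraction)
  list(t_ms = t_ms, wrist = wrist, aperture = ap)
}

arrays_to_trial <- function(arr, subject_id, trial_id, cond, linguistic_error,
                            noise_sd = 0) {
  half <- arr$aperture / 2
  index <- arr$wrist + outer(half, GRIP_AXIS)
  thumb <- arr$wrist - outer(half, GRIP_AXIS)
  n <- length(arr$t_ms)
  if (noise_sd > 0) {
    arr$wrist <- arr$wrist + matrix(stats::rnorm(3L * n, sd = noise_sd), n, 3L)
    index <- index + matrix(stats::rnorm(3L * n, sd = noise_sd), n, 3L)
    thumb <- thumb + matrix(stats::rnorm(3L * n, sd = noise_sd), n, 3L)
  }
  mk <- function(m) structure(list(t_ms = arr$t_ms, x_mm = m[, 1L],
                                   y_mm = m[, 2L], z_mm = m[, 3L]),
                              class = "trajectory")
  trial_record(subject_id, trial_id, cond,
               markers = list(wrist = mk(arr$wrist), index = mk(index),
                              thumb = mk(thumb)),
               linguistic_error = linguistic_error)
}

# ---------------------------------------------------------------------------
# calibration of underlying profile parameters to the segmentation rules
#
# Threshold-based onset/offset rules only see the movement once it is
# fast enough, so the rule-defined reach time is shorter than the
# support of the underlying speed profile and the rule-defined peak
# latency is shifted. The generator therefore defines its ground truth
# in terms of what the study's own segmentation rules measure, and
# calibrates the underlying (duration, peak fraction) so the
# phase-averaged detected parameters equal the requested ones. The
# calibration is solved on a small grid spanning the configured
# condition means plus their variability and interpolated bilinearly;
# it is cached per configuration.

.calibration_cache <- new.env(parent = emptyenv())

calibration_key <- function(config, seg_cfg) {
  paste(collapse = "|", c(
    config$sampling_rate_hz, config$reach_amplitude_mm,
    config$baseline_aperture_mm, config$aperture_peak_fraction,
    config$record_pre_ms, config$record_post_ms, config$rt_mean_ms,
    config$rt_sd_ms, config$n_trials_per_condition,
    seg_cfg$variant, seg_cfg$displacement_threshold_mm,
    seg_cfg$velocity_threshold_mm_s, seg_cfg$filter_cutoff_hz,
    seg_cfg$filter_order, seg_cfg$displacement_mode,
    seg_cfg$grasp_offset_mode,
    grid_ranges_key(config),
    paste(signif(unlist(config$condition_means[PARAM_NAMES]), 8), collapse = ",")
  ))
}

# With no reaction-time spread and no parameter variability, every
# trial of a cell realizes exactly the cell means and its onset phase
# is one of the stratified dither offsets: the calibration can then be
# solved exactly at the six cell targets (no interpolation).
exact_calibration_mode <- function(config) {
  config$rt_sd_ms == 0 &&
    config$between_subject_sd$reach_time_ms == 0 &&
    config$between_subject_sd$pct_t_vpeak == 0 &&
    config$trial_sd$reach_time_ms == 0 &&
    config$trial_sd$pct_t_vpeak == 0
}

dither_phases <- function(m, dt) ((seq_len(m) - 0.5) / m - 0.5) * dt

grid_ranges <- function(config) {
  spread <- function(p) {
    4 * sqrt(config$between_subject_sd[[p]]^2 + config$trial_sd[[p]]^2)
  }
  cm <- config$condition_means
  t_rng <- range(cm$reach_time_ms, cm$grasp_time_ms) + c(-1, 1) * max(spread("reach_time_ms"), 20)
  p_rng <- range(cm$pct_t_vpeak) + c(-1, 1) * max(spread("pct_t_vpeak"), 1)
  p_rng <- c(max(p_rng[1], 5), min(p_rng[2], 95))
  list(t = t_rng, p = p_rng)
}

grid_ranges_key <- function(config) {
  r <- grid_ranges(config)
  paste(signif(c(r$t, r$p), 8), collapse = "|")
}

# mean detected (reach time, pct, grasp time) over a stratified set of
# sub-frame onset phases, for underlying parameters `under`
detected_means <- function(under, config, seg_cfg, phases) {
  cond <- condition("I", "AV")
  acc <- c(0, 0, 0)
  for (ph in phases) {
    arr <- build_trial_arrays(under, config$rt_mean_ms + ph, config)
    trial <- arrays_to_trial(arr, "cal", "cal", cond, FALSE, noise_sd = 0)
    row <- process_trial(trial, seg_cfg)
    if (isTRUE(row$segmentation_failure) || is.na(row$reach_time_ms)) {
      return(NULL)
    }
    g <- if (is.na(row$grasp_time_ms)) under$Tg_u else row$grasp_time_ms
    acc <- acc + c(row$reach_time_ms, row$pct_t_vpeak, g)
  }
  acc / length(phases)
}

# solve the underlying parameters reproducing the target detected values
solve_underlying <- function(T_star, p_star, Tg_star, ap, config, seg_cfg,
                             phases, start = NULL) {
  dt <- 1000 / config$sampling_rate_hz
  under <- start %||% list(T_u = T_star, pf_u = p_star / 100, Tg_u = Tg_star,
                           ap = ap)
  under$ap <- ap
  for (iter in 1:25) {
    d <- detected_means(under, config, seg_cfg, phases)
    if (is.null(d)) {
      # detection failed: widen the underlying profile and retry
      under$T_u <- under$T_u * 1.2
      under$Tg_u <- under$Tg_u * 1.2
      next
    }
    r_T <- T_star - d[1]
    r_p <- p_star - d[2]
    r_g <- Tg_star - d[3]
    if (abs(r_T) < 0.15 && abs(r_p) < 0.01 && abs(r_g) < 0.5) break
    under$T_u <- max(under$T_u + r_T, 10 * dt)
    under$Tg_u <- max(under$Tg_u + r_g, 10 * dt)
    under$pf_u <- min(max(under$pf_u + r_p / 100 * d[1] / under$T_u, 0.02), 0.98)
  }
  under
}

build_calibration <- function(config, seg_cfg, n_t = 9L, n_p = 9L,
                              n_phases = 16L) {
  dt <- 1000 / config$sampling_rate_hz
  ap <- mean(config$condition_means$max_aperture_mm)
  if (exact_calibration_mode(config)) {
    # solve each condition cell exactly, with the same stratified phase
    # set the simulated trials will use
    phases <- dither_phases(config$n_trials_per_condition, dt)
    cm <- config$condition_means
    nodes <- unique(cm[, c("reach_time_ms", "pct_t_vpeak", "grasp_time_ms")])
    sol <- vector("list", nrow(nodes))
    for (i in seq_len(nrow(nodes))) {
      sol[[i]] <- solve_underlying(nodes$reach_time_ms[i], nodes$pct_t_vpeak[i],
                                   nodes$grasp_time_ms[i], ap, config, seg_cfg,
                                   phases)
    }
    return(list(mode = "exact", nodes = nodes, solutions = sol))
  }
  phases <- dither_phases(n_phases, dt)
  rng <- grid_ranges(config)
  t_grid <- seq(rng$t[1], rng$t[2], length.out = n_t)
  p_grid <- seq(rng$p[1], rng$p[2], length.out = n_p)
  corr_T <- corr_p <- corr_g <- matrix(0, n_t, n_p)
  prev_corr <- NULL
  for (i in seq_len(n_t)) {
    for (j in seq_len(n_p)) {
      # warm start from the previously solved node's corrections
      start <- if (is.null(prev_corr)) NULL else {
        list(T_u = t_grid[i] + prev_corr[1L],
             pf_u = min(max(p_grid[j] / 100 + prev_corr[2L], 0.02), 0.98),
             Tg_u = t_grid[i] + prev_corr[3L], ap = ap)
      }
      u <- solve_underlying(t_grid[i], p_grid[j], t_grid[i], ap, config,
                            seg_cfg, phases, start = start)
      corr_T[i, j] <- u$T_u - t_grid[i]
      corr_p[i, j] <- u$pf_u - p_grid[j] / 100
      corr_g[i, j] <- u$Tg_u - t_grid[i]
      prev_corr <- c(corr_T[i, j], corr_p[i, j], corr_g[i, j])
    }
  }
  list(mode = "grid", t_grid = t_grid, p_grid = p_grid,
       corr_T = corr_T, corr_p = corr_p, corr_g = corr_g)
}

get_calibration <- function(config, seg_cfg) {
  key <- calibration_key(config, seg_cfg)
  if (is.null(.calibration_cache[[key]])) {
    .calibration_cache[[key]] <- build_calibration(config, seg_cfg)
  }
  .calibration_cache[[key]]
}

bilinear <- function(grid_x, grid_y, z, x, y) {
  x <- min(max(x, grid_x[1]), grid_x[length(grid_x)])
  y <- min(max(y, grid_y[1]), grid_y[length(grid_y)])
  i <- max(1L, min(findInterval(x, grid_x), length(grid_x) - 1L))
  j <- max(1L, min(findInterval(y, grid_y), length(grid_y) - 1L))
  fx <- (x - grid_x[i]) / (grid_x[i + 1L] - grid_x[i])
  fy <- (y - grid_y[j]) / (grid_y[j + 1L] - grid_y[j])
  (1 - fx) * (1 - fy) * z[i, j] + fx * (1 - fy) * z[i + 1L, j] +
    (1 - fx) * fy * z[i, j + 1L] + fx * fy * z[i + 1L, j + 1L]
}

# map target (detected) parameters to underlying profile parameters
apply_calibration <- function(cal, T_t, p_t, Tg_t) {
  if (is.null(cal)) {
    return(list(T_u = T_t, pf_u = p_t / 100, Tg_u = Tg_t))
  }
  if (identical(cal$mode, "exact")) {
    d <- abs(cal$nodes$reach_time_ms - T_t) + abs(cal$nodes$pct_t_vpeak - p_t) +
      abs(cal$nodes$grasp_time_ms - Tg_t)
    u <- cal$solutions[[which.min(d)]]
    return(list(T_u = u$T_u, pf_u = u$pf_u, Tg_u = u$Tg_u))
  }
  list(
    T_u = T_t + bilinear(cal$t_grid, cal$p_grid, cal$corr_T, T_t, p_t),
    pf_u = min(max(p_t / 100 +
                     bilinear(cal$t_grid, cal$p_grid, cal$corr_p, T_t, p_t),
                   0.02), 0.98),
    Tg_u = Tg_t + bilinear(cal$t_grid, cal$p_grid, cal$corr_g, T_t, p_t)
  )
}

segmentation_for <- function(config) {
  segmentation_config(default_variant(config$sampling_rate_hz))
}

# ---------------------------------------------------------------------------
# public simulators

#' Simulate a single reach-to-grasp trial
#'
#' Generates the three marker trajectories of one trial whose
#' rule-defined kinematic parameters (reach time, normalized
#' velocity-peak latency, grasp time, maximal aperture) equal the
#' configured condition means plus the supplied subject offsets plus
#' trial-level deviations, before position noise. "Rule-defined" means
#' the generator is calibrated so that the segmentation variant matching
#' the configured sampling rate recovers the requested values (averaged
#' over sub-frame onset phases); see the package vignette.
#'
#' @param cond A [condition()] giving the trial's cell.
#' @param subject_offsets Named numeric vector/list of subject-level
#'   offsets for `reach_time_ms`, `pct_t_vpeak`, `max_aperture_mm`
#'   (missing entries are 0).
#' @param config A [generator_config()].
#' @param seed Integer seed; the trial is fully reproducible.
#' @param rt_offset_ms Deterministic shift added to the reaction time
#'   (used by [simulate_experiment()] for stratified sub-frame
#'   dithering).
#' @param subject_id,trial_id Identifiers stored in the record.
#' @param calibrate If `FALSE`, the underlying profile parameters are
#'   used verbatim instead of being calibrated to the segmentation rules.
#' @return A [trial_record()].
#' @export
simulate_trial <- function(cond, subject_offsets = NULL,
                           config = generator_config(), seed = config$seed,
                           rt_offset_ms = 0, subject_id = "S01",
                           trial_id = "T001", calibrate = TRUE) {
  stopifnot(inherits(cond, "condition"), inherits(config, "generator_config"))
  cm <- config$condition_means
  row <- cm[cm$pronoun == cond$pronoun & cm$verb_type == cond$verb_type, ]
  if (nrow(row) != 1L) {
    stop("condition cell ", cond$pronoun, "/", cond$verb_type,
         " missing from `condition_means`", call. = FALSE)
  }
  off <- function(p) {
    v <- subject_offsets[[p]]
    if (is.null(v) || is.na(v)) 0 else v
  }
  set.seed(stream_seed(seed))
  z <- stats::rnorm(4L)
  err <- stats::runif(1L) < config$linguistic_error_rate

  cal <- if (calibrate) get_calibration(config, segmentation_for(config)) else NULL
  rng <- grid_ranges(config)
  T_t <- row$reach_time_ms + off("reach_time_ms") + config$trial_sd$reach_time_ms * z[1]
  T_t <- min(max(T_t, rng$t[1]), rng$t[2])
  p_t <- row$pct_t_vpeak + off("pct_t_vpeak") + config$trial_sd$pct_t_vpeak * z[2]
  p_t <- min(max(p_t, rng$p[1]), rng$p[2])
  # the grasp window tracks the reach window: shared deviation
  Tg_t <- row$grasp_time_ms + (T_t - row$reach_time_ms)
  ap_t <- row$max_aperture_mm + off("max_aperture_mm") +
    config$trial_sd$max_aperture_mm * z[3]
  ap_t <- max(ap_t, config$baseline_aperture_mm + 5)

  under <- apply_calibration(cal, T_t, p_t, Tg_t)
  under$ap <- ap_t
  rt <- max(config$rt_mean_ms + config$rt_sd_ms * z[4] + rt_offset_ms, 60)
  arr <- build_trial_arrays(under, rt, config)
  arrays_to_trial(arr, subject_id, trial_id, cond, err,
                  noise_sd = config$trial_noise_sd_mm)
}

#' Simulate a complete within-subject experiment
#'
#' Generates `n_subjects` blocks of trials: every (pronoun, verb type)
#' cell receives `n_trials_per_condition` critical trials, plus catch
#' trials according to `catch_fraction` (catch trials are kinematically
#' identical to critical trials -- participants still reached -- and are
#' flagged for exclusion). Subject-level parameter offsets are drawn
#' once per subject; trial order is randomized within subject. Across
#' the trials of one cell, reaction times carry stratified sub-frame
#' offsets so that frame quantization of the threshold rules averages
#' out in cell means.
#'
#' @param config A [generator_config()].
#' @param seed Master seed; the full dataset is reproducible
#'   byte-for-byte.
#' @param calibrate Passed to [simulate_trial()].
#' @return A `trial_dataset`.
#' @examples
#' ds <- simulate_experiment(generator_preset("exp1_italian", n_subjects = 1))
#' @export
simulate_experiment <- function(config = generator_config(), seed = config$seed,
                                calibrate = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  if (calibrate) get_calibration(config, segmentation_for(config))
  dt <- 1000 / config$sampling_rate_hz
  m <- config$n_trials_per_condition
  n_critical <- 6L * m
  n_catch <- round(n_critical * config$catch_fraction / (1 - config$catch_fraction))
  cells <- expand.grid(pronoun = PRONOUNS, verb_type = VERB_TYPES,
                       stringsAsFactors = FALSE)
  verbs <- config_verbs(config)

  trials <- vector("list", config$n_subjects * (n_critical + n_catch))
  k <- 0L
  for (s in seq_len(config$n_subjects)) {
    set.seed(stream_seed(seed, subject = s))
    offsets <- list(
      reach_time_ms = stats::rnorm(1L, sd = config$between_subject_sd$reach_time_ms),
      pct_t_vpeak = stats::rnorm(1L, sd = config$between_subject_sd$pct_t_vpeak),
      max_aperture_mm = stats::rnorm(1L, sd = config$between_subject_sd$max_aperture_mm)
    )
    plan <- vector("list", n_critical + n_catch)
    i <- 0L
    for (ci in seq_len(nrow(cells))) {
      labels <- verbs$verb[verbs$verb_type == cells$verb_type[ci]]
      for (j in seq_len(m)) {
        i <- i + 1L
        plan[[i]] <- list(
          cond = condition(cells$pronoun[ci], cells$verb_type[ci],
                           verb = labels[(j - 1L) %% length(labels) + 1L]),
          dither = ((j - 0.5) / m - 0.5) * dt
        )
      }
    }
    for (j in seq_len(n_catch)) {
      i <- i + 1L
      ci <- (j - 1L) %% nrow(cells) + 1L
      labels <- verbs$verb[verbs$verb_type == cells$verb_type[ci]]
      plan[[i]] <- list(
        cond = condition(cells$pronoun[ci], cells$verb_type[ci],
                         verb = labels[(j - 1L) %% length(labels) + 1L],
                         is_catch = TRUE),
        dither = ((j - 0.5) / max(n_catch, 1L) - 0.5) * dt
      )
    }
    ord <- sample.int(length(plan))
    subject_id <- sprintf("S%02d", s)
    for (pos in seq_along(ord)) {
      p <- plan[[ord[pos]]]
      k <- k + 1L
      trials[[k]] <- simulate_trial(
        p$cond, offsets, config,
        seed = stream_seed(seed, subject = s, counter = pos),
        rt_offset_ms = p$dither,
        subject_id = subject_id,
        trial_id = sprintf("T%03d", pos),
        calibrate = calibrate
      )
    }
  }
  new_trial_dataset(trials, config = config)
}

config_verbs <- function(config) {
  exp <- if (config$sampling_rate_hz >= 120) "exp2" else "exp1"
  tab <- tryCatch(stimulus_verbs(exp), error = function(e) NULL)
  if (is.null(tab) || !nrow(tab)) {
    return(data.frame(verb = c(paste0("av", 1:5), paste0("iv", 1:5)),
                      verb_type = rep(c("AV", "IV"), each = 5)))
  }
  data.frame(verb = tab$infinitive, verb_type = tab$verb_type)
}
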