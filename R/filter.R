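#' Zero-phase low-pass filtering of a kinematic series
#'
#' Applies a Butterworth low-pass filter forward and backward so the
#' output has zero phase lag, the standard way position data from
#' motion-capture systems are smoothed before differentiation.
#' The series is extended at both ends by odd-symmetric reflection so
#' that start-up transients fall outside the observation window.
#'
#' @param series Numeric vector, one uniformly sampled signal.
#' @param rate_hz Sampling rate in Hz.
#' @param cutoff_hz Filter cutoff frequency in Hz; must be below the
#'   Nyquist frequency `rate_hz / 2`.
#' @param order Filter order of a single pass (default 2). The
#'   forward-backward application squares the magnitude response, so the
#'   effective attenuation is that of a filter of twice this order.
#' @return Numeric vector of the same length as `series`.
#' @examples
#' x <- sin(2 * pi * 2 * (0:59) / 60) + rnorm(60, sd = 0.1)
#' y <- lowpass(x, rate_hz = 60, cutoff_hz = 10)
#' @export
lowpass <- function(series, rate_hz, cutoff_hz = 10, order = 2) {
  if (!is.numeric(series) || anyNA(series)) {
    stop("`series` must be a numeric vector without missing values", call. = FALSE)
  }
  check_positive(rate_hz, "rate_hz")
  check_positive(cutoff_hz, "cutoff_hz")
  if (!is.numeric(order) || length(order) != 1L || order < 1 || order != round(order)) {
    stop("`order` must be a positive integer", call. = FALSE)
  }
  if (cutoff_hz >= rate_hz / 2) {
    stop("`cutoff_hz` must be below the Nyquist frequency (rate_hz / 2)", call. = FALSE)
  }
  ba <- butter_coefficients(order, cutoff_hz, rate_hz)
  n_min <- filtfilt_padding(order) + 2L
  if (length(series) < n_min) {
    stop("`series` is too short to filter (need at least ", n_min, " samples)",
         call. = FALSE)
  }
  .zero_phase_cpp(as.numeric(series), ba$b, ba$a, filtfilt_padding(order))
}

# Butterworth design is delegated to signal::butter; coefficients are
# cached because the same (order, cutoff, rate) triple is reused for
# every series of a dataset.
butter_coefficients <- local({
  cache <- new.env(parent = emptyenv())
  function(order, cutoff_hz, rate_hz) {
    key <- paste(order, cutoff_hz, rate_hz, sep = "|")
    if (is.null(cache[[key]])) {
      bf <- signal::butter(order, cutoff_hz / (rate_hz / 2), type = "low")
      cache[[key]] <- list(b = as.numeric(bf$b), a = as.numeric(bf$a))
    }
    cache[[key]]
  }
})

filtfilt_padding <- function(order) 3L * (order + 1L)

# Matrix convenience used on the hot path: filters each column with the
# same coefficients in one C++ call.
lowpass_mat <- function(mat, rate_hz, cutoff_hz, order) {
  ba <- butter_coefficients(order, cutoff_hz, rate_hz)
  .zero_phase_mat_cpp(mat, ba$b, ba$a, filtfilt_padding(order))
}

#' Tangential speed of a marker trajectory
#'
#' Differentiates each Cartesian axis (central differences in the
#' interior, one-sided at the endpoints) and returns the Euclidean norm
#' of the three velocity components, i.e. the tangential speed used to
#' locate the velocity peak of the reach.
#'
#' @param traj A [trajectory()] object.
#' @return Numeric vector of speeds in mm/s, one per frame.
#' @export
marker_speed <- function(traj) {
  traj <- as_trajectory(traj)
  n <- length(traj$t_ms)
  if (n < 3L) {
    stop("speed requires at least 3 frames", call. = FALSE)
  }
  xyz <- cbind(traj$x_mm, traj$y_mm, traj$z_mm)
  t_s <- traj$t_ms / 1000
  v <- deriv_central(xyz, t_s)
  sqrt(rowSums(v * v))
}

deriv_central <- function(xyz, t_s) {
  n <- nrow(xyz)
  v <- matrix(0, n, ncol(xyz))
  idx <- 2:(n - 1)
  dt2 <- t_s[idx + 1L] - t_s[idx - 1L]
  v[idx, ] <- (xyz[idx + 1L, , drop = FALSE] - xyz[idx - 1L, , drop = FALSE]) / dt2
  v[1L, ] <- (xyz[2L, ] - xyz[1L, ]) / (t_s[2L] - t_s[1L])
  v[n, ] <- (xyz[n, ] - xyz[n - 1L, ]) / (t_s[n] - t_s[n - 1L])
  v
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop("`", name, "` must be a single positive finite number", call. = FALSE)
  }
  invisible(x)
}
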