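#' Unimodal bell-shaped speed profile with a controllable peak latency
#'
#' Generates the tangential speed series of a point-to-point reach as a
#' beta-family bell, `v(tau) = K * tau^a * (1 - tau)^b` with
#' `a = s * peak_fraction`, `b = s * (1 - peak_fraction)` and shape
#' total `s = 4`, scaled so the time integral equals the movement
#' amplitude. The single `peak_fraction` parameter places the velocity
#' peak at that fraction of the movement duration; at
#' `peak_fraction = 0.5` the profile reduces to the symmetric
#' minimum-jerk speed profile `v = (30 D / T) tau^2 (1 - tau)^2`, whose
#' peak speed is `1.875 * D / T`.
#'
#' @param peak_fraction Location of the speed maximum as a fraction of
#'   the duration, strictly in (0, 1).
#' @param duration_ms Movement duration in ms.
#' @param amplitude_mm Path length of the movement in mm.
#' @param rate_hz Sampling rate in Hz.
#' @return Numeric vector of speeds (mm/s), sampled at `rate_hz` from
#'   t = 0 to `duration_ms` inclusive; zero at both ends.
#' @examples
#' v <- speed_profile(0.5, 742.6, 330, 60)
#' max(v) # ~ 1.875 * 330 / 0.7426
#' @export
speed_profile <- function(peak_fraction, duration_ms, amplitude_mm, rate_hz) {
  check_peak_fraction(peak_fraction)
  check_positive(duration_ms, "duration_ms")
  check_positive(amplitude_mm, "amplitude_mm")
  check_positive(rate_hz, "rate_hz")
  n <- profile_n_samples(duration_ms, rate_hz)
  if (n < 10L) {
    stop("`duration_ms` must yield at least 10 samples at `rate_hz`", call. = FALSE)
  }
  tau <- seq(0, 1, length.out = n)
  beta_speed(tau, peak_fraction, duration_ms, amplitude_mm)
}

# Speed of the beta-family bell at normalized time tau in [0, 1].
# dbeta(tau, a + 1, b + 1) integrates to 1 over tau, so dividing by the
# duration (in s) and multiplying by the amplitude conserves path length
# exactly; its mode sits at a / (a + b) = peak_fraction.
beta_speed <- function(tau, peak_fraction, duration_ms, amplitude_mm,
                       shape_total = 4) {
  a <- shape_total * peak_fraction
  b <- shape_total * (1 - peak_fraction)
  amplitude_mm / (duration_ms / 1000) * stats::dbeta(tau, a + 1, b + 1)
}

# Path length covered up to normalized time tau: the closed-form beta
# CDF, so simulated positions carry no numerical-integration error.
beta_path <- function(tau, peak_fraction, amplitude_mm, shape_total = 4) {
  a <- shape_total * peak_fraction
  b <- shape_total * (1 - peak_fraction)
  amplitude_mm * stats::pbeta(tau, a + 1, b + 1)
}

profile_n_samples <- function(duration_ms, rate_hz) {
  floor(duration_ms * rate_hz / 1000 + 1e-9) + 1L
}

check_peak_fraction <- function(x) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0 || x >= 1) {
    stop("`peak_fraction` must be a single number strictly in (0, 1)", call. = FALSE)
  }
  invisible(x)
}

#' Grip aperture profile
#'
#' Generates the index-thumb distance series of a grasp: the aperture
#' opens from a resting baseline to a unique maximum located at
#' `peak_fraction` of the grasp duration and closes back to baseline,
#' following the same beta-family bell as [speed_profile()] rescaled to
#' peak exactly at `max_aperture_mm`.
#'
#' @param baseline_mm Resting inter-marker distance (mm), e.g. the pinch
#'   posture at trial start.
#' @param max_aperture_mm Maximal finger aperture (mm); must exceed the
#'   baseline.
#' @param peak_fraction Location of the aperture maximum as a fraction
#'   of the duration, strictly in (0, 1).
#' @param duration_ms Grasp duration in ms.
#' @param rate_hz Sampling rate in Hz.
#' @return Numeric vector of apertures (mm), `baseline_mm` at both ends.
#' @export
aperture_profile <- function(baseline_mm, max_aperture_mm, peak_fraction,
                             duration_ms, rate_hz) {
  check_positive(baseline_mm, "baseline_mm")
  check_peak_fraction(peak_fraction)
  check_positive(duration_ms, "duration_ms")
  check_positive(rate_hz, "rate_hz")
  if (!is.numeric(max_aperture_mm) || length(max_aperture_mm) != 1L ||
      !is.finite(max_aperture_mm) || max_aperture_mm <= baseline_mm) {
    stop("`max_aperture_mm` must exceed `baseline_mm`", call. = FALSE)
  }
  n <- profile_n_samples(duration_ms, rate_hz)
  if (n < 10L) {
    stop("`duration_ms` must yield at least 10 samples at `rate_hz`", call. = FALSE)
  }
  tau <- seq(0, 1, length.out = n)
  aperture_bump(tau, baseline_mm, max_aperture_mm, peak_fraction)
}

aperture_bump <- function(tau, baseline_mm, max_aperture_mm, peak_fraction,
                          shape_total = 4) {
  a <- shape_total * peak_fraction
  b <- shape_total * (1 - peak_fraction)
  w <- tau^a * (1 - tau)^b / (peak_fraction^a * (1 - peak_fraction)^b)
  baseline_mm + (max_aperture_mm - baseline_mm) * w
}
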