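#' Bi-exponential twitch waveform shape
#'
#' A twitch (evoked torque or radial displacement) is modelled as a delayed
#' bi-exponential pulse
#' \deqn{x(t) = A \, \frac{e^{-(t-d)/\tau_{decay}} - e^{-(t-d)/\tau_{rise}}}{c}, \quad t \ge d,}
#' where \eqn{c} rescales the pulse so that its maximum equals the amplitude
#' \eqn{A}. This is the standard parsimonious description of a single muscle
#' twitch: a fast rising phase, a slower relaxation phase, and a latency
#' between the electrical stimulus and mechanical onset.
#'
#' @param amplitude Peak value in native units (Nm for torque, mm for
#'   displacement). Must be non-negative.
#' @param tau_rise Rise time constant in ms; must satisfy
#'   `0 < tau_rise < tau_decay`.
#' @param tau_decay Decay time constant in ms.
#' @param onset_delay Latency from stimulus to mechanical onset in ms
#'   (non-negative).
#'
#' @return An object of class `twitch_shape`.
#' @examples
#' sh <- twitch_shape(20, tau_rise = 10, tau_decay = 80, onset_delay = 20)
#' peak_time(sh)
#' @export
twitch_shape <- function(amplitude, tau_rise, tau_decay, onset_delay = 0) {
  if (!is.numeric(amplitude) || amplitude < 0) {
    abort("`amplitude` must be non-negative.", class = "tmg_invalid_config")
  }
  if (!(tau_rise > 0 && tau_decay > tau_rise)) {
    abort("Time constants must satisfy 0 < tau_rise < tau_decay.",
          class = "tmg_invalid_config")
  }
  if (onset_delay < 0) {
    abort("`onset_delay` must be non-negative.", class = "tmg_invalid_config")
  }
  structure(
    list(amplitude = amplitude, tau_rise = tau_rise,
         tau_decay = tau_decay, onset_delay = onset_delay),
    class = "twitch_shape"
  )
}

#' @export
print.twitch_shape <- function(x, ...) {
  cat(sprintf(
    "<twitch_shape> A = %.3g, tau_rise = %.3g ms, tau_decay = %.3g ms, onset = %.3g ms\n",
    x$amplitude, x$tau_rise, x$tau_decay, x$onset_delay))
  invisible(x)
}

#' Analytic peak time of a bi-exponential twitch
#'
#' The unscaled pulse \eqn{e^{-s/\tau_d} - e^{-s/\tau_r}} attains its maximum
#' at \eqn{s^\ast = \frac{\tau_r \tau_d}{\tau_d - \tau_r}\ln(\tau_d/\tau_r)}
#' after onset; `peak_time()` returns the peak time measured from the
#' stimulus, i.e. onset delay plus \eqn{s^\ast}.
#'
#' @param shape A [twitch_shape()].
#' @return Peak time in ms from the stimulus.
#' @export
peak_time <- function(shape) {
  stopifnot(inherits(shape, "twitch_shape"))
  s <- with(shape, tau_rise * tau_decay / (tau_decay - tau_rise) *
              log(tau_decay / tau_rise))
  shape$onset_delay + s
}

# Peak value of the unscaled pulse exp(-s/td) - exp(-s/tr), used to rescale
# the waveform so its maximum equals the configured amplitude.
biexp_peak_norm <- function(tau_rise, tau_decay) {
  s <- tau_rise * tau_decay / (tau_decay - tau_rise) *
    log(tau_decay / tau_rise)
  exp(-s / tau_decay) - exp(-s / tau_rise)
}

#' Sample a twitch waveform
#'
#' Evaluates the rescaled bi-exponential pulse of a [twitch_shape()] on a
#' regular time grid. The trace is exactly zero before the onset delay and
#' its sampled maximum equals the configured amplitude up to grid resolution.
#'
#' @param shape A [twitch_shape()].
#' @param duration_ms Trace duration in ms. Should be at least
#'   `5 * tau_decay + onset_delay` so the pulse decays essentially to zero
#'   (< 1% of the amplitude) within the trace.
#' @param sample_rate Sampling rate in Hz (> 0).
#'
#' @return A tibble with columns `time_s` (seconds, starting at 0) and
#'   `value` (native units).
#' @examples
#' sh <- twitch_shape(20, 10, 80, onset_delay = 20)
#' w <- twitch_waveform(sh, duration_ms = 500, sample_rate = 1000)
#' max(w$value)
#' @export
twitch_waveform <- function(shape, duration_ms, sample_rate) {
  stopifnot(inherits(shape, "twitch_shape"))
  if (!is.numeric(sample_rate) || sample_rate <= 0) {
    abort("`sample_rate` must be positive.", class = "tmg_invalid_config")
  }
  if (duration_ms < 5 * shape$tau_decay + shape$onset_delay) {
    warn("`duration_ms` is shorter than 5 * tau_decay + onset_delay; the twitch may be truncated.")
  }
  n <- floor(duration_ms / 1000 * sample_rate) + 1L
  t_s <- seq(0, by = 1 / sample_rate, length.out = n)
  tibble::tibble(time_s = t_s,
                 value = eval_twitch(shape, t_s * 1000))
}

# Evaluate the shape at arbitrary times (ms from stimulus); vectorised.
eval_twitch <- function(shape, t_ms) {
  out <- numeric(length(t_ms))
  if (shape$amplitude == 0) return(out)
  s <- t_ms - shape$onset_delay
  on <- s > 0
  norm <- biexp_peak_norm(shape$tau_rise, shape$tau_decay)
  out[on] <- shape$amplitude *
    (exp(-s[on] / shape$tau_decay) - exp(-s[on] / shape$tau_rise)) / norm
  out
}

# Dimensionless rising-limb crossing time: for the unit-amplitude pulse with
# tau_rise = 1 and tau_decay = ratio, the time (in units of tau_rise) at which
# the rising limb first reaches `level` (fraction of the peak). Times of the
# pulse scale linearly with tau_rise at a fixed tau_decay/tau_rise ratio, so
# these unit crossings calibrate shapes to target delay/contraction times.
unit_rise_crossing <- function(level, ratio) {
  stopifnot(level > 0, level < 1, ratio > 1)
  t_peak <- ratio / (ratio - 1) * log(ratio)
  norm <- exp(-t_peak / ratio) - exp(-t_peak)
  f <- function(u) (exp(-u / ratio) - exp(-u)) / norm - level
  stats::uniroot(f, c(1e-9, t_peak), tol = 1e-12)$root
}

# Solve for (tau_rise, onset_delay) so that the displacement waveform has the
# requested 10%-crossing delay (td_ms) and 10-90% rise time (tc_ms), at a
# fixed decay/rise ratio. Negative implied onsets are clamped to zero.
shape_for_timing <- function(amplitude, td_ms, tc_ms, ratio = 6) {
  u10 <- unit_rise_crossing(0.10, ratio)
  u90 <- unit_rise_crossing(0.90, ratio)
  tau_rise <- tc_ms / (u90 - u10)
  onset <- max(0, td_ms - tau_rise * u10)
  twitch_shape(amplitude, tau_rise, ratio * tau_rise, onset)
}
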