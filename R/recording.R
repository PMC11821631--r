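#' A stimulus-locked twitch recording
#'
#' Bundles the synchronously sampled traces of one evoked twitch: dynamometer
#' torque, TMG radial displacement, and the stimulator trigger channel,
#' together with the sampling rate and the sample index of the stimulus.
#'
#' @param torque Numeric torque trace (Nm, or volts before calibration).
#' @param displacement Numeric radial displacement trace (mm).
#' @param trigger Numeric trigger trace (arbitrary units; a short pulse marks
#'   each stimulus).
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param stim_index Sample index (1-based) of the stimulus.
#'
#' @return An object of class `twitch_recording`.
#' @export
twitch_recording <- function(torque, displacement, trigger, sample_rate,
                             stim_index) {
  n <- length(torque)
  if (length(displacement) != n || length(trigger) != n) {
    abort("All traces of a twitch recording must have the same length.",
          class = "tmg_invalid_config")
  }
  if (!is.numeric(sample_rate) || sample_rate <= 0) {
    abort("`sample_rate` must be positive.", class = "tmg_invalid_config")
  }
  if (stim_index < 1 || stim_index > n) {
    abort("`stim_index` must lie within the trace.",
          class = "tmg_invalid_config")
  }
  structure(
    list(torque = as.numeric(torque),
         displacement = as.numeric(displacement),
         trigger = as.numeric(trigger),
         sample_rate = sample_rate,
         stim_index = as.integer(stim_index)),
    class = "twitch_recording"
  )
}

#' @export
print.twitch_recording <- function(x, ...) {
  cat(sprintf("<twitch_recording> %d samples @ %g Hz, stimulus at sample %d\n",
              length(x$torque), x$sample_rate, x$stim_index))
  invisible(x)
}

#' @rdname twitch_recording
#' @param x Object to coerce/print.
#' @return `as_tibble()` returns the recording as a tibble with columns
#'   `time_s`, `torque_Nm`, `trigger`, `displacement_mm`.
#' @export
as_tibble.twitch_recording <- function(x, ...) {
  tibble::tibble(
    time_s = (seq_along(x$torque) - 1) / x$sample_rate,
    torque_Nm = x$torque,
    trigger = x$trigger,
    displacement_mm = x$displacement
  )
}
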