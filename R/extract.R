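#' Convert a dynamometer voltage trace to torque
#'
#' Applies the daily calibration factor (Nm per volt) elementwise.
#'
#' @param voltage_trace Numeric trace in volts.
#' @param calibration_factor Calibration factor in Nm/V (> 0).
#' @return Numeric torque trace in Nm.
#' @export
calibrate_torque <- function(voltage_trace, calibration_factor) {
  if (!is.numeric(calibration_factor) || calibration_factor <= 0) {
    abort("`calibration_factor` must be positive.",
          class = "tmg_invalid_calibration")
  }
  voltage_trace * calibration_factor
}

#' Locate stimulus pulses in a trigger trace
#'
#' A stimulus is the first sample at or above `threshold` following a sample
#' below it (a rising edge). Returns all such indices in ascending order;
#' an empty integer vector when no edge crosses the threshold.
#'
#' @param trigger_trace Numeric trigger trace.
#' @param threshold Detection threshold.
#' @return Integer vector of stimulus sample indices.
#' @examples
#' tr <- c(0, 0, 1, 1, 0, 0, 1, 0)
#' detect_triggers(tr, 0.5)
#' @export
detect_triggers <- function(trigger_trace, threshold = 0.5) {
  x <- trigger_trace
  if (length(x) < 2) return(integer(0))
  which(x[-1] >= threshold & x[-length(x)] < threshold) + 1L
}

#' Rolling-median MVIC torque
#'
#' The MVIC of a voluntary contraction is the highest value of a centred
#' rolling median (default window 501 samples) among window centres lying in
#' the period during which the raw torque exceeds `floor` (default 20 Nm).
#' Only full windows are considered (centres closer than half a window to
#' either trace edge are excluded). If the torque never exceeds the floor,
#' no MVIC is defined and `NA` is returned.
#'
#' @param torque_trace Numeric torque trace in Nm.
#' @param window Rolling-median window width in samples (odd; default 501).
#' @param floor Minimum torque in Nm defining the contraction period.
#' @return MVIC torque in Nm, or `NA_real_` when the trace never exceeds
#'   `floor`.
#' @export
extract_mvic <- function(torque_trace, window = 501, floor = 20) {
  n <- length(torque_trace)
  if (window %% 2 == 0) {
    abort("`window` must be odd.", class = "tmg_invalid_config")
  }
  if (n < window) {
    abort("Trace is shorter than the rolling-median window.",
          class = "tmg_invalid_config")
  }
  h <- (window - 1L) / 2L
  rm <- runmed(torque_trace, window, endrule = "keep")
  centres <- (h + 1L):(n - h)
  valid <- centres[torque_trace[centres] > floor]
  if (length(valid) == 0) return(NA_real_)
  max(rm[valid])
}

#' Twitch peak torque
#'
#' Filters the torque trace with a zero-phase low-pass Butterworth filter
#' (default 4th order, 15 Hz cut-off), subtracts the pre-stimulus baseline
#' (mean of the filtered trace over the `baseline_ms` preceding the
#' stimulus) and returns the maximum within the analysis window after the
#' stimulus.
#'
#' @param recording A [twitch_recording()].
#' @param analysis_window_ms Post-stimulus window searched for the peak (ms).
#' @param baseline_ms Pre-stimulus span averaged as the baseline (ms).
#' @param cutoff,order Butterworth filter settings (see [filter_twitch()]).
#' @return Peak twitch torque `Pt` in Nm.
#' @export
twitch_peak_torque <- function(recording, analysis_window_ms = 300,
                               baseline_ms = 50, cutoff = 15, order = 4) {
  stopifnot(inherits(recording, "twitch_recording"))
  fs <- recording$sample_rate
  stim <- recording$stim_index
  win_n <- round(analysis_window_ms / 1000 * fs)
  if (stim + win_n > length(recording$torque)) {
    abort("Analysis window exceeds the trace.", class = "tmg_invalid_config")
  }
  filt <- filter_twitch(recording$torque, fs, cutoff = cutoff, order = order)
  base_n <- min(stim - 1L, round(baseline_ms / 1000 * fs))
  baseline <- if (base_n > 0) mean(filt[(stim - base_n):(stim - 1L)]) else 0
  max(filt[stim:(stim + win_n)]) - baseline
}

#' TMG displacement parameters of one twitch
#'
#' Extracts, from the radial displacement trace of a stimulus-locked
#' recording:
#' * `Dm` (mm): height of the first post-stimulus local maximum whose
#'   prominence exceeds `max(noise_floor, 5%% of the global maximum)`,
#'   falling back to the global maximum if no local peak qualifies;
#' * `Td` (ms): time from the stimulus to the first upward crossing of
#'   10% of `Dm`;
#' * `Tc` (ms): time from that crossing to the first upward crossing of
#'   90% of `Dm`.
#'
#' Crossings are located with sub-sample precision by linear interpolation
#' between adjacent samples. The pre-stimulus mean is subtracted first. If
#' the maximal displacement stays below `min_displacement` the sensor is
#' deemed to have detected no displacement and all three parameters are
#' `NA` (flagged, not an error).
#'
#' @param recording A [twitch_recording()].
#' @param min_displacement Minimum peak displacement in mm for the twitch to
#'   count as detected.
#' @param noise_floor Minimum peak prominence in mm.
#' @param baseline_ms Pre-stimulus span averaged as the baseline (ms).
#' @return A one-row tibble with columns `Dm`, `Td`, `Tc` and the logical
#'   flag `no_displacement`.
#' @export
displacement_params <- function(recording, min_displacement = 0.1,
                                noise_floor = 0.05, baseline_ms = 50) {
  stopifnot(inherits(recording, "twitch_recording"))
  fs <- recording$sample_rate
  stim <- recording$stim_index
  x <- recording$displacement
  base_n <- min(stim - 1L, round(baseline_ms / 1000 * fs))
  if (base_n > 0) x <- x - mean(x[(stim - base_n):(stim - 1L)])

  seg <- x[stim:length(x)]
  gmax <- max(seg)
  if (!is.finite(gmax) || gmax < min_displacement) {
    return(tibble::tibble(Dm = NA_real_, Td = NA_real_, Tc = NA_real_,
                          no_displacement = TRUE))
  }

  peaks <- local_maxima(seg)
  prom_min <- max(noise_floor, 0.05 * gmax)
  peak_rel <- NA_integer_
  for (p in peaks) {
    if (peak_prominence(seg, p) > prom_min) { peak_rel <- p; break }
  }
  if (is.na(peak_rel)) peak_rel <- which.max(seg)
  dm <- seg[peak_rel]
  peak_abs <- stim + peak_rel - 1L

  t10 <- first_upward_crossing(x, stim, peak_abs, 0.10 * dm)
  if (is.na(t10)) {
    return(tibble::tibble(Dm = dm, Td = NA_real_, Tc = NA_real_,
                          no_displacement = FALSE))
  }
  t90 <- first_upward_crossing(x, stim, peak_abs, 0.90 * dm)
  td <- (t10 - stim) / fs * 1000
  tc <- (t90 - t10) / fs * 1000
  tibble::tibble(Dm = dm, Td = td, Tc = tc, no_displacement = FALSE)
}

# indices of strict-left / weak-right local maxima (first sample of a
# plateau wins)
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[x[i] > x[i - 1] & x[i] >= x[i + 1]]
}

# topographic prominence of the peak at index p: height above the higher of
# the two saddle minima towards the nearest higher ground (or segment edge)
peak_prominence <- function(x, p) {
  n <- length(x)
  higher_l <- which(x[seq_len(p - 1)] > x[p])
  lo_l <- if (length(higher_l) == 0) min(x[1:p]) else
    min(x[(max(higher_l)):p])
  right <- if (p < n) x[(p + 1):n] else numeric(0)
  higher_r <- which(right > x[p])
  lo_r <- if (length(higher_r) == 0) min(x[p:n]) else
    min(x[p:(p + min(higher_r))])
  x[p] - max(lo_l, lo_r)
}

# fractional (1-based) sample position of the first upward crossing of
# `level` between trace indices `from` and `to`; NA if none
first_upward_crossing <- function(x, from, to, level) {
  if (to <= from) {
    return(if (x[from] >= level) as.numeric(from) else NA_real_)
  }
  idx <- from:to
  below <- x[idx[-length(idx)]] < level
  above <- x[idx[-1]] >= level
  hit <- which(below & above)
  if (length(hit) == 0) {
    return(if (x[from] >= level) as.numeric(from) else NA_real_)
  }
  i <- idx[hit[1]]
  i + (level - x[i]) / (x[i + 1] - x[i])
}

#' Extract twitch parameters from a cohort
#'
#' Runs [twitch_peak_torque()] and [displacement_params()] on every
#' (subject, timepoint) recording of a simulated or loaded cohort and
#' returns the long-format parameter table consumed by the reliability,
#' inference and diagnostics stages.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param ... Passed on to [twitch_peak_torque()] and
#'   [displacement_params()] (e.g. `cutoff`, `min_displacement`).
#' @return A tibble with columns `subject`, `timepoint` (factor in schedule
#'   order), `Pt`, `Dm`, `Td`, `Tc`, `no_displacement`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_subjects = 2, seed = 1))
#' extract_parameters(cohort)
#' @export
extract_parameters <- function(cohort, ...) {
  stopifnot(inherits(cohort, "tmg_cohort"))
  dots <- list(...)
  pt_args <- dots[names(dots) %in%
                    c("analysis_window_ms", "baseline_ms", "cutoff", "order")]
  dp_args <- dots[names(dots) %in%
                    c("min_displacement", "noise_floor", "baseline_ms")]
  rows <- purrr::map(cohort$sessions, function(s) {
    purrr::imap(s$recordings, function(rec, tp) {
      dp <- do.call(displacement_params, c(list(rec), dp_args))
      dplyr::bind_cols(
        tibble::tibble(
          subject = s$subject_id, timepoint = tp,
          Pt = do.call(twitch_peak_torque, c(list(rec), pt_args))),
        dp)
    }) %>% dplyr::bind_rows()
  }) %>% dplyr::bind_rows()
  rows$timepoint <- factor(rows$timepoint, levels = cohort$config$schedule)
  rows
}

#' Extract MVIC torque and fatigue index per subject
#'
#' Applies the rolling-median MVIC definition to the first and last
#' voluntary-contraction trace of each session and computes the fatigue
#' index, the percent decline from the first to the last MVIC.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param window,floor Passed to [extract_mvic()].
#' @return A tibble with columns `subject`, `first_mvic`, `last_mvic`, `fi`.
#' @export
extract_fatigue <- function(cohort, window = 501, floor = 20) {
  stopifnot(inherits(cohort, "tmg_cohort"))
  purrr::map(cohort$sessions, function(s) {
    first <- extract_mvic(s$mvic_traces[[1]], window, floor)
    last <- extract_mvic(s$mvic_traces[[length(s$mvic_traces)]], window, floor)
    tibble::tibble(subject = s$subject_id, first_mvic = first,
                   last_mvic = last,
                   fi = if (is.na(first) || is.na(last)) NA_real_ else
                     fatigue_index(first, last))
  }) %>% dplyr::bind_rows()
}
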