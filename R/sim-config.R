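#' Default measurement schedule
#'
#' Two baseline twitches (`Pre1`, `Pre2`), one twitch after each of the seven
#' exercise sets (`Set1`--`Set7`), one immediately after the last set
#' (`Post0`), one a minute later (`Post1`) and then one every two minutes
#' until 15 min post-exercise.
#'
#' @return Character vector of timepoint labels.
#' @export
default_schedule <- function() {
  c("Pre1", "Pre2", paste0("Set", 1:7),
    paste0("Post", c(0, 1, 3, 5, 7, 9, 11, 13, 15)))
}

#' Simulation configuration for a potentiation--fatigue session cohort
#'
#' Collects every knob of the synthetic-session generator. The defaults
#' emulate a cohort of 16 resistance-trained adults performing 60 maximal
#' voluntary isometric knee extensions: baseline twitch parameters are drawn
#' from the observed baseline distributions (peak twitch torque
#' 19.47 +/- 8.49 Nm, displacement 3.06 +/- 1.86 mm, delay time
#' 20.45 +/- 9.96 ms, contraction time 21.64 +/- 2.41 ms), peak twitch torque
#' follows a potentiation-then-fatigue trajectory (+44.1% after the first
#' set, -32.9% after the last set, -26.4% residual at 15 min), and the MVIC
#' fatigue index is distributed as 39.8% +/- 11.5%.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param sample_rate Sampling rate in Hz for all traces.
#' @param schedule Ordered character vector of timepoint labels; must contain
#'   `Pre1`, `Pre2` and at least one post-exercise label (`Set*` or `Post*`).
#' @param baseline_means,baseline_sds Named numeric vectors (`Pt`, `Dm`,
#'   `Td`, `Tc`) giving the population mean and the between-subject SD of
#'   each baseline twitch parameter.
#' @param within_subject_sd Within-subject (trial-to-trial) coefficient of
#'   variation; either a single number or a named vector per parameter.
#'   Applied as multiplicative lognormal noise so values stay positive. The
#'   defaults are the relative standard errors of measurement of each
#'   parameter (2.6% for Pt, 12.3% for Dm, 25.5% for Td, 3.7% for Tc).
#' @param potentiation_peak Fractional Pt gain after the first set
#'   (0.441 = +44.1%).
#' @param fatigue_floor Fractional Pt loss after the last set (0.329).
#' @param recovery_residual Fractional Pt loss remaining 15 min
#'   post-exercise (0.264).
#' @param displacement_coupling Fraction of the torque trajectory that is
#'   transmitted to the displacement amplitude: Dm is multiplied by
#'   `1 + displacement_coupling * (m - 1)` where `m` is the Pt multiplier.
#'   Values < 1 emulate an attenuated displacement response (long muscle
#'   length / low signal-to-noise); 1 means displacement tracks torque fully.
#' @param mvic_start Mean first-contraction MVIC plateau in Nm.
#' @param fi_mean,fi_sd Mean and SD (%) of the per-subject MVIC fatigue
#'   index; draws are truncated to `[0, 100]`.
#' @param torque_noise_sd,displacement_noise_sd Additive Gaussian noise SD on
#'   the raw traces (Nm / mm). Default 0: the generator's primary noise
#'   channel is the amplitude-level lognormal noise, and clean traces keep
#'   the extracted parameters exactly reproducible; raise these to probe
#'   signal-to-noise effects on the extraction stage.
#' @param twitch_duration_ms Duration of each twitch recording (ms).
#' @param stim_offset_ms Time of the stimulus within each recording (ms).
#' @param seed Integer seed; all randomness in [simulate_cohort()] flows from
#'   it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_subjects = 4, seed = 1)
#' cfg$schedule
#' @export
sim_config <- function(n_subjects = 16,
                       sample_rate = 1000,
                       schedule = default_schedule(),
                       baseline_means = c(Pt = 19.47, Dm = 3.06,
                                          Td = 20.45, Tc = 21.64),
                       baseline_sds = c(Pt = 8.49, Dm = 1.86,
                                        Td = 9.96, Tc = 2.41),
                       within_subject_sd = c(Pt = 0.026, Dm = 0.123,
                                             Td = 0.255, Tc = 0.037),
                       potentiation_peak = 0.441,
                       fatigue_floor = 0.329,
                       recovery_residual = 0.264,
                       displacement_coupling = 0.5,
                       mvic_start = 220,
                       fi_mean = 39.8,
                       fi_sd = 11.5,
                       torque_noise_sd = 0,
                       displacement_noise_sd = 0,
                       twitch_duration_ms = 600,
                       stim_offset_ms = 100,
                       seed = NULL) {
  if (n_subjects < 2) {
    abort("`n_subjects` must be at least 2.", class = "tmg_invalid_config")
  }
  if (sample_rate <= 0) {
    abort("`sample_rate` must be positive.", class = "tmg_invalid_config")
  }
  if (!all(c("Pre1", "Pre2") %in% schedule)) {
    abort("`schedule` must contain Pre1 and Pre2.",
          class = "tmg_invalid_config")
  }
  if (!any(grepl("^(Set|Post)", schedule))) {
    abort("`schedule` must contain at least one post-exercise label.",
          class = "tmg_invalid_config")
  }
  pars <- c("Pt", "Dm", "Td", "Tc")
  if (!all(pars %in% names(baseline_means)) ||
      !all(pars %in% names(baseline_sds))) {
    abort("`baseline_means` and `baseline_sds` need entries Pt, Dm, Td, Tc.",
          class = "tmg_invalid_config")
  }
  if (length(within_subject_sd) == 1 && is.null(names(within_subject_sd))) {
    within_subject_sd <- stats::setNames(rep(within_subject_sd, 4), pars)
  }
  if (!all(pars %in% names(within_subject_sd))) {
    abort("`within_subject_sd` must be a scalar or named per parameter.",
          class = "tmg_invalid_config")
  }
  for (f in c(potentiation_peak, fatigue_floor, recovery_residual,
              displacement_coupling)) {
    if (f < 0 || f > 1) {
      abort("Trajectory fractions must lie in [0, 1].",
            class = "tmg_invalid_config")
    }
  }
  structure(
    list(n_subjects = as.integer(n_subjects), sample_rate = sample_rate,
         schedule = schedule, baseline_means = baseline_means[pars],
         baseline_sds = baseline_sds[pars],
         within_subject_sd = within_subject_sd[pars],
         potentiation_peak = potentiation_peak, fatigue_floor = fatigue_floor,
         recovery_residual = recovery_residual,
         displacement_coupling = displacement_coupling,
         mvic_start = mvic_start, fi_mean = fi_mean, fi_sd = fi_sd,
         torque_noise_sd = torque_noise_sd,
         displacement_noise_sd = displacement_noise_sd,
         twitch_duration_ms = twitch_duration_ms,
         stim_offset_ms = stim_offset_ms, seed = seed),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0("<sim_config> %d subjects, %g Hz, %d timepoints\n",
           "  Pt trajectory: +%.1f%% (Set1), -%.1f%% (Set7), -%.1f%% (Post15)\n",
           "  displacement coupling: %.2f; seed: %s\n"),
    x$n_subjects, x$sample_rate, length(x$schedule),
    100 * x$potentiation_peak, 100 * x$fatigue_floor,
    100 * x$recovery_residual, x$displacement_coupling,
    if (is.null(x$seed)) "none" else format(x$seed)))
  invisible(x)
}

#' Deterministic potentiation--fatigue trajectory multiplier
#'
#' Maps a timepoint label to the unitless multiplier applied to each
#' subject's baseline peak twitch torque. Baselines sit at 1; the first set
#' jumps to `1 + potentiation_peak`; the multiplier then declines linearly
#' over the remaining sets to `1 - fatigue_floor` at the last set; during
#' recovery it rises linearly (in minutes) to `1 - recovery_residual` at the
#' last post-exercise timepoint.
#'
#' @param timepoint Character vector of labels from the schedule (`Pre*`,
#'   `Set<k>`, `Post<min>`).
#' @param config A [sim_config()].
#' @return Numeric vector of multipliers.
#' @examples
#' cfg <- sim_config()
#' trajectory_multiplier(c("Pre2", "Set1", "Set7", "Post15"), cfg)
#' @export
trajectory_multiplier <- function(timepoint, config) {
  stopifnot(inherits(config, "sim_config"))
  unknown <- setdiff(timepoint, config$schedule)
  if (length(unknown) > 0) {
    abort(paste0("Unknown timepoint label(s): ",
                 paste(unknown, collapse = ", ")),
          class = "tmg_unknown_timepoint")
  }
  sets <- sort(as.integer(sub("^Set", "", grep("^Set", config$schedule,
                                               value = TRUE))))
  posts <- sort(as.numeric(sub("^Post", "", grep("^Post", config$schedule,
                                                 value = TRUE))))
  top <- 1 + config$potentiation_peak
  floor_m <- 1 - config$fatigue_floor
  end_m <- 1 - config$recovery_residual
  vapply(timepoint, function(tp) {
    if (grepl("^Pre", tp)) return(1)
    if (grepl("^Set", tp)) {
      k <- as.integer(sub("^Set", "", tp))
      if (length(sets) == 1) return(top)
      frac <- (k - min(sets)) / (max(sets) - min(sets))
      return(top + frac * (floor_m - top))
    }
    m <- as.numeric(sub("^Post", "", tp))
    if (length(posts) == 1 || max(posts) == min(posts)) return(end_m)
    frac <- (m - min(posts)) / (max(posts) - min(posts))
    floor_m + frac * (end_m - floor_m)
  }, numeric(1), USE.NAMES = FALSE)
}
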