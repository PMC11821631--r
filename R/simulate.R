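#' Simulate a cohort of potentiation--fatigue sessions
#'
#' Generates, for each subject, a full measurement session: one
#' stimulus-triggered twitch recording (torque + displacement + trigger) per
#' scheduled timepoint, plus voluntary-contraction torque traces for the
#' first and last MVIC of the exercise protocol.
#'
#' Subject-level baseline parameters (`Pt`, `Dm`, `Td`, `Tc`) are drawn from
#' truncated normal distributions with the configured means and
#' between-subject SDs. At each timepoint the torque amplitude is the
#' subject's baseline times the deterministic [trajectory_multiplier()] times
#' multiplicative lognormal within-subject noise; the displacement amplitude
#' uses the attenuated multiplier `1 + displacement_coupling * (m - 1)`.
#' Timing parameters (`Td`, `Tc`) carry within-subject noise but no
#' systematic trajectory. MVIC plateaus decline so that each subject's
#' fatigue index is a truncated normal draw from the configured distribution.
#'
#' All randomness flows from `config$seed` (or the `seed` argument); the
#' caller's RNG state is left untouched.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer overriding `config$seed`.
#'
#' @return An object of class `tmg_cohort`: a list with elements `sessions`
#'   (one `session_recording` per subject), `truth` (a tibble of the
#'   noise-realised true parameter values per subject and timepoint, plus the
#'   per-subject fatigue index) and `config`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_subjects = 3, seed = 42))
#' cohort$truth
#' @export
simulate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- seed %||% config$seed
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }

  mu <- config$baseline_means
  sb <- config$baseline_sds
  cv <- config$within_subject_sd
  fs <- config$sample_rate
  mult <- trajectory_multiplier(config$schedule, config)
  names(mult) <- config$schedule

  sessions <- vector("list", config$n_subjects)
  truth_rows <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    sid <- sprintf("S%02d", i)
    base <- c(
      Pt = rtruncnorm1(mu[["Pt"]], sb[["Pt"]], lower = 1),
      Dm = rtruncnorm1(mu[["Dm"]], sb[["Dm"]], lower = 0.2),
      Td = rtruncnorm1(mu[["Td"]], sb[["Td"]], lower = 3),
      Tc = rtruncnorm1(mu[["Tc"]], sb[["Tc"]], lower = 8)
    )
    # torque waveform timing: physiological twitch, mild per-subject spread
    tq_tau_rise <- 25 * exp(rnorm(1, 0, 0.08))
    tq_ratio <- 4.8
    tq_delay <- 8 * exp(rnorm(1, 0, 0.1))

    recs <- vector("list", length(config$schedule))
    names(recs) <- config$schedule
    tp_truth <- vector("list", length(config$schedule))
    for (j in seq_along(config$schedule)) {
      tp <- config$schedule[[j]]
      m <- mult[[tp]]
      md <- 1 + config$displacement_coupling * (m - 1)
      pt_t <- base[["Pt"]] * m * lnoise(cv[["Pt"]])
      dm_t <- base[["Dm"]] * md * lnoise(cv[["Dm"]])
      td_t <- base[["Td"]] * lnoise(cv[["Td"]])
      tc_t <- base[["Tc"]] * lnoise(cv[["Tc"]])
      recs[[j]] <- build_twitch_recording(
        pt = pt_t, dm = dm_t, td = td_t, tc = tc_t,
        tq_tau_rise = tq_tau_rise, tq_ratio = tq_ratio, tq_delay = tq_delay,
        config = config)
      tp_truth[[j]] <- tibble::tibble(
        subject = sid, timepoint = tp,
        Pt = pt_t, Dm = dm_t, Td = td_t, Tc = tc_t)
    }

    fi <- rtruncnorm1(config$fi_mean, config$fi_sd, lower = 0, upper = 100)
    first_plateau <- config$mvic_start * exp(rnorm(1, 0, 0.15))
    last_plateau <- first_plateau * (1 - fi / 100)
    mvic <- list(
      Set1_rep1 = build_mvic_trace(first_plateau, fs),
      Set7_rep10 = build_mvic_trace(last_plateau, fs)
    )

    sessions[[i]] <- structure(
      list(subject_id = sid, recordings = recs, mvic_traces = mvic,
           sample_rate = fs),
      class = "session_recording")
    truth_rows[[i]] <- dplyr::bind_rows(tp_truth) %>%
      dplyr::mutate(fi = fi)
  }

  structure(
    list(sessions = sessions,
         truth = dplyr::bind_rows(truth_rows),
         config = config),
    class = "tmg_cohort")
}

#' @export
print.tmg_cohort <- function(x, ...) {
  cat(sprintf("<tmg_cohort> %d subjects x %d timepoints @ %g Hz\n",
              length(x$sessions), length(x$config$schedule),
              x$config$sample_rate))
  invisible(x)
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf("<session_recording> %s: %d twitch recordings, %d MVIC traces\n",
              x$subject_id, length(x$recordings), length(x$mvic_traces)))
  invisible(x)
}

# one truncated-normal draw by rejection (bounds are far in the tail for the
# default configurations, so this rarely iterates)
rtruncnorm1 <- function(mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(min(max(mean, lower), upper))
  repeat {
    x <- rnorm(1, mean, sd)
    if (x >= lower && x <= upper) return(x)
  }
}

# multiplicative lognormal noise factor with unit median
lnoise <- function(cv) if (cv == 0) 1 else rlnorm(1, 0, cv)

# assemble one stimulus-locked twitch recording from realised parameters
build_twitch_recording <- function(pt, dm, td, tc, tq_tau_rise, tq_ratio,
                                   tq_delay, config) {
  fs <- config$sample_rate
  n <- floor(config$twitch_duration_ms / 1000 * fs) + 1L
  stim_index <- as.integer(round(config$stim_offset_ms / 1000 * fs)) + 1L
  t_ms <- (seq_len(n) - stim_index) * 1000 / fs  # ms from stimulus

  tq_shape <- twitch_shape(pt, tq_tau_rise, tq_ratio * tq_tau_rise, tq_delay)
  disp_shape <- shape_for_timing(dm, td, tc)

  torque <- eval_twitch(tq_shape, t_ms)
  displacement <- eval_twitch(disp_shape, t_ms)
  if (config$torque_noise_sd > 0) {
    torque <- torque + rnorm(n, 0, config$torque_noise_sd)
  }
  if (config$displacement_noise_sd > 0) {
    displacement <- displacement + rnorm(n, 0, config$displacement_noise_sd)
  }
  trigger <- numeric(n)
  pulse <- stim_index:min(n, stim_index + max(1L, round(fs / 1000)) - 1L)
  trigger[pulse] <- 1  # 1 ms rectangular pulse at the stimulus

  twitch_recording(torque, displacement, trigger, fs, stim_index)
}

# trapezoidal MVIC torque trace: ramp up, hold, ramp down
build_mvic_trace <- function(plateau, sample_rate, plateau_s = 2,
                             ramp_s = 0.4, pad_s = 0.3) {
  ramp_n <- round(ramp_s * sample_rate)
  up <- seq(0, plateau, length.out = ramp_n)
  hold <- rep(plateau, round(plateau_s * sample_rate))
  down <- seq(plateau, 0, length.out = ramp_n)
  pad <- rep(0, round(pad_s * sample_rate))
  c(pad, up, hold, down, pad)
}

#' Write a cohort to delimited files
#'
#' Writes one CSV per (subject, timepoint) twitch recording with columns
#' `time_s`, `torque_Nm`, `trigger`, `displacement_mm`, plus a cohort
#' manifest (`manifest.csv`: subject, timepoint, file) and the configuration
#' as a key-value text file (`config.txt`).
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest tibble.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "tmg_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (s in cohort$sessions) {
    for (tp in names(s$recordings)) {
      f <- file.path(dir, sprintf("%s_%s.csv", s$subject_id, tp))
      readr::write_csv(as_tibble.twitch_recording(s$recordings[[tp]]), f)
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject = s$subject_id, timepoint = tp, file = basename(f))
    }
  }
  manifest <- dplyr::bind_rows(rows)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  cfg <- cohort$config
  flat <- vapply(cfg, function(v) paste(format(v), collapse = ","),
                 character(1))
  writeLines(paste0(names(flat), " = ", flat), file.path(dir, "config.txt"))
  invisible(manifest)
}

#' Read a twitch recording from a delimited signal file
#'
#' Expects the layout written by [write_cohort()]: columns `time_s`,
#' `torque_Nm`, `trigger`, `displacement_mm`, one row per sample on a regular
#' grid. The stimulus index is located from the trigger channel's first
#' rising edge.
#'
#' @param path Path to the CSV file.
#' @param trigger_threshold Threshold for the trigger rising edge.
#' @return A [twitch_recording()].
#' @export
read_session_csv <- function(path, trigger_threshold = 0.5) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("time_s", "torque_Nm", "trigger", "displacement_mm")
  if (!all(need %in% names(d))) {
    abort(paste("Signal file must have columns:", paste(need, collapse = ", ")),
          class = "tmg_invalid_config")
  }
  fs <- 1 / median(diff(d$time_s))
  idx <- detect_triggers(d$trigger, trigger_threshold)
  if (length(idx) == 0) {
    abort("No trigger pulse found in signal file.",
          class = "tmg_invalid_config")
  }
  twitch_recording(d$torque_Nm, d$displacement_mm, d$trigger, fs, idx[[1]])
}
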