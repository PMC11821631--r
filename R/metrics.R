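#' Contraction-velocity parameters from displacement timing
#'
#' Derives the four mean rates of displacement used alongside the primary
#' TMG parameters (`Dm` in mm, `Td` and `Tc` in ms):
#' \deqn{Vc_{0-10} = 0.1 \, Dm / Td \times 1000}
#' \deqn{Vc_{0-90} = 0.9 \, Dm / (Td + Tc) \times 1000}
#' \deqn{Vc_{10-90} = 0.8 \, Dm / Tc \times 1000}
#' \deqn{Vc_{norm} = 0.8 / Tc \times 1000}
#' The first three are in mm/s; `Vc_norm` is amplitude-normalised (1/s). By
#' construction `Vc_10_90 = Dm * Vc_norm` exactly.
#'
#' @param Dm Displacement amplitude in mm (>= 0).
#' @param Td Delay time in ms (> 0).
#' @param Tc Contraction time in ms (> 0).
#' @return A tibble with columns `Vc0_10`, `Vc0_90`, `Vc10_90`, `Vcnorm`.
#'   Vectorised over its arguments; `NA` inputs yield `NA` outputs.
#' @examples
#' vc_parameters(Dm = 1, Td = 100, Tc = 100)
#' @export
vc_parameters <- function(Dm, Td, Tc) {
  bad <- (!is.na(Td) & Td <= 0) | (!is.na(Tc) & Tc <= 0)
  if (any(bad)) {
    abort("`Td` and `Tc` must be positive.", class = "tmg_undefined_parameter")
  }
  tibble::tibble(
    Vc0_10 = 0.1 * Dm / Td * 1000,
    Vc0_90 = 0.9 * Dm / (Td + Tc) * 1000,
    Vc10_90 = 0.8 * Dm / Tc * 1000,
    Vcnorm = 0.8 / Tc * 1000
  )
}

#' Append contraction-velocity columns to a parameter table
#'
#' @param params A tibble with columns `Dm`, `Td`, `Tc` (e.g. from
#'   [extract_parameters()]).
#' @return `params` with `Vc0_10`, `Vc0_90`, `Vc10_90`, `Vcnorm` appended.
#' @export
add_vc_parameters <- function(params) {
  stopifnot(all(c("Dm", "Td", "Tc") %in% names(params)))
  dplyr::bind_cols(params, vc_parameters(params$Dm, params$Td, params$Tc))
}

#' Fatigue index
#'
#' Percent decline of MVIC torque from the first to the last voluntary
#' contraction: `FI = 100 * (first - last) / first`.
#'
#' @param first_mvic First-contraction MVIC in Nm (> 0).
#' @param last_mvic Last-contraction MVIC in Nm.
#' @return Fatigue index in percent (vectorised).
#' @examples
#' fatigue_index(250, 150)
#' @export
fatigue_index <- function(first_mvic, last_mvic) {
  if (any(first_mvic <= 0, na.rm = TRUE)) {
    abort("`first_mvic` must be positive.", class = "tmg_invalid_config")
  }
  100 * (first_mvic - last_mvic) / first_mvic
}

#' Percent change from a baseline value
#'
#' `100 * (value - baseline) / baseline`; a zero baseline yields `NA` with a
#' warning rather than an error, mirroring how undefined per-subject changes
#' are flagged downstream.
#'
#' @param value,baseline Numeric vectors (recycled).
#' @return Percent change (vectorised).
#' @examples
#' percent_change(144.1, 100)
#' @export
percent_change <- function(value, baseline) {
  out <- 100 * (value - baseline) / baseline
  zero <- !is.na(baseline) & baseline == 0
  if (any(zero)) {
    warn("Zero baseline: percent change undefined, returning NA.")
    out[zero] <- NA_real_
  }
  out
}

#' Per-subject percent changes from a baseline timepoint
#'
#' Pivots a parameter table to long format and expresses every value as the
#' percent change from the same subject's value at `baseline`.
#'
#' @param params Tibble with columns `subject`, `timepoint` and one column
#'   per parameter (as returned by [extract_parameters()] /
#'   [add_vc_parameters()]).
#' @param baseline Baseline timepoint label (default `"Pre2"`).
#' @param parameters Character vector of parameter columns; defaults to all
#'   numeric columns except bookkeeping ones.
#' @return A long tibble with columns `subject`, `timepoint`, `parameter`,
#'   `value`, `baseline_value`, `delta`, `pct_change`.
#' @export
percent_change_table <- function(params, baseline = "Pre2",
                                 parameters = NULL) {
  stopifnot(all(c("subject", "timepoint") %in% names(params)))
  if (is.null(parameters)) {
    parameters <- setdiff(names(params)[vapply(params, is.numeric, logical(1))],
                          c("subject"))
  }
  long <- params %>%
    tidyr::pivot_longer(dplyr::all_of(parameters),
                        names_to = "parameter", values_to = "value")
  base <- long %>%
    dplyr::filter(.data$timepoint == baseline) %>%
    dplyr::select("subject", "parameter", baseline_value = "value")
  long %>%
    dplyr::left_join(base, by = c("subject", "parameter")) %>%
    dplyr::mutate(delta = .data$value - .data$baseline_value,
                  pct_change = 100 * .data$delta / .data$baseline_value)
}
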