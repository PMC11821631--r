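#' Flag extreme values by the Tukey 3 x IQR rule
#'
#' A value is extreme when it lies below `Q1 - 3 * IQR` or above
#' `Q3 + 3 * IQR`. Quartiles use the default linear-interpolation convention
#' (`stats::quantile()` type 7). A constant vector has zero IQR, the fences
#' collapse onto the constant and nothing is flagged.
#'
#' @param values Numeric vector (length >= 4 recommended).
#' @param k Fence multiplier (default 3, the "extreme value" rule).
#' @return Logical vector, `TRUE` where extreme; `NA` values are never
#'   flagged.
#' @examples
#' flag_extremes(c(1, 2, 3, 4, 100))
#' @export
flag_extremes <- function(values, k = 3) {
  q <- quantile(values, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  iqr <- q[2] - q[1]
  out <- values < q[1] - k * iqr | values > q[2] + k * iqr
  out[is.na(out)] <- FALSE
  out
}

#' Interpolate interior missing values in a per-subject series
#'
#' Each missing value is replaced by the mean of the nearest preceding and
#' nearest following observed values of the same series; a run of
#' consecutive missing values therefore gets the same replacement. Missing
#' values at either end have no neighbour on one side and raise an error.
#'
#' @param series Time-ordered numeric vector with `NA` for missing entries.
#' @return The series with all `NA`s filled.
#' @examples
#' interpolate_missing(c(1, NA, 3))
#' interpolate_missing(c(2, NA, NA, 8))
#' @export
interpolate_missing <- function(series) {
  miss <- which(is.na(series))
  if (length(miss) == 0) return(series)
  obs <- which(!is.na(series))
  if (length(obs) == 0 || miss[1] < obs[1] || miss[length(miss)] > obs[length(obs)]) {
    abort("Missing values at the series boundary cannot be interpolated.",
          class = "tmg_unresolvable_missing")
  }
  out <- series
  for (i in miss) {
    prev <- max(obs[obs < i])
    nxt <- min(obs[obs > i])
    out[i] <- (series[prev] + series[nxt]) / 2
  }
  out
}

#' One-way within-subjects repeated-measures ANOVA
#'
#' Decomposes a complete subjects-by-timepoints matrix into subject, time
#' and error sums of squares and tests the time effect with a
#' sphericity-corrected F-test. The Greenhouse--Geisser epsilon is estimated
#' from the sample covariance of the repeated measures via an orthonormal
#' contrast; the default Huynh--Feldt correction applies the standard
#' debiasing of the Greenhouse--Geisser estimate (truncated at 1), which
#' keeps the type-I error at its nominal level when sphericity in fact
#' holds. Both corrected degrees of freedom are fractional in general.
#' Partial eta squared is `SS_time / (SS_time + SS_error)`.
#'
#' @param data Data frame in long format.
#' @param value,subject,timepoint Columns (tidy-select) holding the
#'   measurement, the subject id and the timepoint label.
#' @param correction Sphericity correction: `"huynh-feldt"` (default),
#'   `"greenhouse-geisser"`, or `"none"`.
#' @return A `tmg_rm_anova` object with [tidy()] and [glance()] methods.
#' @examples
#' d <- tidyr::expand_grid(subject = factor(1:6), timepoint = factor(1:4))
#' d$value <- rnorm(nrow(d)) + as.integer(d$timepoint)
#' fit <- rm_anova(d, value, subject, timepoint)
#' glance(fit)
#' @export
rm_anova <- function(data, value, subject, timepoint,
                     correction = c("huynh-feldt", "greenhouse-geisser",
                                    "none")) {
  correction <- match.arg(correction)
  v <- as_name(enquo(value))
  s <- as_name(enquo(subject))
  tp <- as_name(enquo(timepoint))
  wide <- data %>%
    dplyr::select(dplyr::all_of(c(s, tp, v))) %>%
    tidyr::pivot_wider(names_from = dplyr::all_of(tp),
                       values_from = dplyr::all_of(v))
  Y <- as.matrix(wide[, -1, drop = FALSE])
  if (anyNA(Y)) {
    abort("Incomplete subjects-by-timepoints matrix; fill gaps with interpolate_missing() first.",
          class = "tmg_incomplete_matrix")
  }
  n <- nrow(Y); k <- ncol(Y)
  if (k < 2 || n < 3) {
    abort("Need at least 3 subjects and 2 timepoints.",
          class = "tmg_invalid_config")
  }
  gm <- mean(Y)
  ss_time <- n * sum((colMeans(Y) - gm)^2)
  ss_subj <- k * sum((rowMeans(Y) - gm)^2)
  ss_err <- sum((Y - gm)^2) - ss_time - ss_subj
  ms_time <- ss_time / (k - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  f_stat <- ms_time / ms_err

  eps_gg <- gg_epsilon(Y)
  eps <- switch(correction,
    "none" = 1,
    "greenhouse-geisser" = eps_gg,
    "huynh-feldt" = {
      den <- (k - 1) * ((n - 1) - (k - 1) * eps_gg)
      # the debiased estimate blows past 1 when the denominator closes; it
      # is conventionally truncated to 1 and can never fall below the GG one
      if (den <= 0) 1 else
        min(1, max(eps_gg, (n * (k - 1) * eps_gg - 2) / den))
    })
  df_num <- eps * (k - 1)
  df_den <- eps * (k - 1) * (n - 1)
  structure(
    list(f_stat = f_stat, df_num = df_num, df_den = df_den,
         p_value = pf(f_stat, df_num, df_den, lower.tail = FALSE),
         partial_eta_sq = ss_time / (ss_time + ss_err),
         epsilon = eps, epsilon_gg = eps_gg, correction = correction,
         n_subjects = n, n_timepoints = k,
         ss = c(time = ss_time, subject = ss_subj, error = ss_err)),
    class = "tmg_rm_anova")
}

# Greenhouse-Geisser epsilon from an orthonormal contrast of the sample
# covariance matrix of the repeated measures.
gg_epsilon <- function(Y) {
  k <- ncol(Y)
  H <- qr.Q(qr(stats::contr.helmert(k)))
  M <- t(H) %*% cov(Y) %*% H
  sum(diag(M))^2 / ((k - 1) * sum(M^2))
}

#' @export
print.tmg_rm_anova <- function(x, ...) {
  cat(sprintf(
    "Within-subjects RM-ANOVA (%s correction)\nF(%.2f, %.2f) = %.3f, p = %.4g, partial eta^2 = %.3f\n",
    x$correction, x$df_num, x$df_den, x$f_stat, x$p_value,
    x$partial_eta_sq))
  invisible(x)
}

#' @rdname rm_anova
#' @param x A `tmg_rm_anova` object.
#' @param ... Unused.
#' @export
tidy.tmg_rm_anova <- function(x, ...) {
  tibble::tibble(term = "timepoint", df_num = x$df_num, df_den = x$df_den,
                 statistic = x$f_stat, p.value = x$p_value,
                 partial_eta_sq = x$partial_eta_sq, epsilon = x$epsilon)
}

#' @rdname rm_anova
#' @export
glance.tmg_rm_anova <- function(x, ...) {
  tibble::tibble(statistic = x$f_stat, p.value = x$p_value,
                 df_num = x$df_num, df_den = x$df_den,
                 partial_eta_sq = x$partial_eta_sq, epsilon = x$epsilon,
                 n_subjects = x$n_subjects, n_timepoints = x$n_timepoints,
                 correction = x$correction)
}

#' Bonferroni-corrected paired comparisons against a baseline timepoint
#'
#' Paired t-test of every post-baseline timepoint against the baseline
#' column, with Bonferroni adjustment `p_adj = min(1, p * m)` (default `m` =
#' number of comparisons) and a bias-corrected effect size per comparison.
#'
#' @param data Long data frame.
#' @param value,subject,timepoint Columns (tidy-select).
#' @param baseline Baseline timepoint label (default `"Pre2"`).
#' @param m Bonferroni family size; defaults to the number of post-baseline
#'   timepoints compared.
#' @return A tibble, one row per compared timepoint: `timepoint`, `n`,
#'   `diff`, `t_stat`, `p_raw`, `p_adj`, `g`, `g_lo`, `g_hi`, `g_band`.
#' @export
bonferroni_vs_baseline <- function(data, value, subject, timepoint,
                                   baseline = "Pre2", m = NULL) {
  v <- as_name(enquo(value))
  s <- as_name(enquo(subject))
  tp <- as_name(enquo(timepoint))
  d <- data %>%
    dplyr::select(subject = dplyr::all_of(s), timepoint = dplyr::all_of(tp),
                  value = dplyr::all_of(v))
  tps <- if (is.factor(d$timepoint)) levels(d$timepoint) else
    unique(as.character(d$timepoint))
  if (!baseline %in% as.character(d$timepoint)) {
    abort("Baseline timepoint not present in the data.",
          class = "tmg_invalid_config")
  }
  base <- d %>% dplyr::filter(.data$timepoint == baseline)
  others <- setdiff(tps[tps %in% as.character(d$timepoint)], baseline)
  # compare only timepoints after the baseline in schedule order
  others <- others[match(others, tps) > match(baseline, tps)]
  m <- m %||% length(others)
  purrr::map(others, function(t2) {
    cmp <- d %>%
      dplyr::filter(.data$timepoint == t2) %>%
      dplyr::inner_join(base, by = "subject", suffix = c("", "_base"))
    x <- cmp$value; y <- cmp$value_base
    pb <- paired_bias(x, y)
    hg <- hedges_g(x, y)
    tibble::tibble(
      timepoint = t2, n = length(x), diff = pb$bias, t_stat = pb$t_stat,
      p_raw = pb$p_value, p_adj = min(1, pb$p_value * m),
      g = hg$g, g_lo = hg$g_lo, g_hi = hg$g_hi, g_band = hg$band)
  }) %>% dplyr::bind_rows()
}

#' Pearson correlation with magnitude banding
#'
#' Product-moment correlation with a two-sided t-test and the |r| magnitude
#' band (thresholds 0.1 / 0.3 / 0.5 / 0.7 / 0.9).
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @return A one-row tibble: `r`, `p_value`, `n`, `band`, `degenerate`
#'   (`TRUE` when either input has zero variance).
#' @export
pearson_assoc <- function(x, y) {
  if (length(x) != length(y)) {
    abort("`x` and `y` must have equal length.", class = "tmg_pairing_error")
  }
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) {
    abort("At least 3 complete pairs are required.",
          class = "tmg_pairing_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble::tibble(r = NA_real_, p_value = NA_real_, n = n,
                          band = NA_character_, degenerate = TRUE))
  }
  r <- cor(x, y)
  p <- if (abs(r) == 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tstat), n - 2)
  }
  tibble::tibble(r = r, p_value = p, n = n, band = correlation_band(r),
                 degenerate = FALSE)
}
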