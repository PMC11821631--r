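#' Paired-samples test for systematic bias between repeated baselines
#'
#' Two-sided paired t-test of `pre1` against `pre2`. If the paired
#' differences have zero variance the t statistic is degenerate: it is
#' reported as 0 with p = 1 when the bias is zero, and as (+/-) `Inf` with
#' p = 0 and a `degenerate` flag otherwise.
#'
#' @param pre1,pre2 Paired numeric vectors (same subjects, same order).
#' @param conf_level Confidence level for the bias CI.
#' @return A one-row tibble: `bias`, `bias_lo`, `bias_hi`, `t_stat`, `df`,
#'   `p_value`, `degenerate`.
#' @export
paired_bias <- function(pre1, pre2, conf_level = 0.95) {
  check_paired(pre1, pre2)
  d <- pre1 - pre2
  n <- length(d)
  if (sd(d) == 0) {
    bias <- mean(d)
    return(tibble::tibble(
      bias = bias, bias_lo = bias, bias_hi = bias,
      t_stat = if (bias == 0) 0 else sign(bias) * Inf,
      df = n - 1,
      p_value = if (bias == 0) 1 else 0,
      degenerate = TRUE))
  }
  tt <- t.test(pre1, pre2, paired = TRUE, conf.level = conf_level)
  tibble::tibble(
    bias = unname(tt$estimate), bias_lo = tt$conf.int[1],
    bias_hi = tt$conf.int[2], t_stat = unname(tt$statistic),
    df = unname(tt$parameter), p_value = tt$p.value, degenerate = FALSE)
}

#' Bias-corrected standardised effect size (Hedges' g) for paired data
#'
#' The raw standardised difference uses the average of the two SDs,
#' `d = (mean1 - mean2) / ((sd1 + sd2) / 2)`, multiplied by the small-sample
#' correction `J = 1 - 3 / (4 (n - 1) - 1)`. The confidence interval is a
#' normal approximation with the paired-design variance
#' `var(d) = (1/n + d^2 / (2 n)) * 2 (1 - r)`, where `r` is the Pearson
#' correlation between the paired measurements (supply `r` explicitly when
#' only summary statistics are available; it defaults to the sample
#' correlation of `pre1` and `pre2`).
#'
#' Magnitude bands: |g| < 0.2 trivial, then small, moderate, large, very
#' large and extremely large at 0.2, 0.6, 1.2, 2.0 and 4.0.
#'
#' @param pre1,pre2 Paired numeric vectors.
#' @param conf_level Confidence level.
#' @param r Correlation between pairs used for the CI; default computed from
#'   the data.
#' @return A one-row tibble: `g`, `g_lo`, `g_hi`, `band`, `degenerate`.
#' @export
hedges_g <- function(pre1, pre2, conf_level = 0.95, r = NULL) {
  check_paired(pre1, pre2)
  n <- length(pre1)
  gs <- hedges_g_summary(mean(pre1), sd(pre1), mean(pre2), sd(pre2), n,
                         r = r %||% suppressWarnings(cor(pre1, pre2)),
                         conf_level = conf_level)
  gs
}

#' @rdname hedges_g
#' @param m1,s1,m2,s2 Means and SDs of the two measurements.
#' @param n Number of pairs.
#' @export
hedges_g_summary <- function(m1, s1, m2, s2, n, r = NULL,
                             conf_level = 0.95) {
  s_av <- (s1 + s2) / 2
  if (s_av == 0) {
    return(tibble::tibble(g = NA_real_, g_lo = NA_real_, g_hi = NA_real_,
                          band = NA_character_, degenerate = TRUE))
  }
  J <- 1 - 3 / (4 * (n - 1) - 1)
  d <- (m1 - m2) / s_av
  g <- J * d
  if (is.null(r) || is.na(r)) {
    lo <- hi <- NA_real_
  } else {
    se <- J * sqrt((1 / n + d^2 / (2 * n)) * 2 * (1 - r))
    z <- qnorm(1 - (1 - conf_level) / 2)
    lo <- g - z * se
    hi <- g + z * se
  }
  tibble::tibble(g = g, g_lo = lo, g_hi = hi,
                 band = effect_band(g), degenerate = FALSE)
}

#' Magnitude bands for standardised effects and correlations
#'
#' `effect_band()` bins |g| at 0.2 / 0.6 / 1.2 / 2.0 / 4.0 into trivial,
#' small, moderate, large, very large and extremely large.
#' `correlation_band()` bins |r| at 0.1 / 0.3 / 0.5 / 0.7 / 0.9 into
#' trivial, small, moderate, large, very large and extremely large.
#' `icc_band()` bins the ICC at 0.5 / 0.75 / 0.9 into poor, moderate, good
#' and excellent relative reliability.
#'
#' @param g,r,icc Numeric values (vectorised).
#' @return Character vector of band labels.
#' @export
effect_band <- function(g) {
  cut(abs(g), breaks = c(-Inf, 0.2, 0.6, 1.2, 2.0, 4.0, Inf),
      labels = c("trivial", "small", "moderate", "large", "very large",
                 "extremely large"),
      right = FALSE) %>% as.character()
}

#' @rdname effect_band
#' @export
correlation_band <- function(r) {
  cut(abs(r), breaks = c(-Inf, 0.1, 0.3, 0.5, 0.7, 0.9, Inf),
      labels = c("trivial", "small", "moderate", "large", "very large",
                 "extremely large"),
      right = FALSE) %>% as.character()
}

#' @rdname effect_band
#' @export
icc_band <- function(icc) {
  cut(icc, breaks = c(-Inf, 0.5, 0.75, 0.9, Inf),
      labels = c("poor", "moderate", "good", "excellent"),
      right = FALSE) %>% as.character()
}

#' Intraclass correlation ICC(A,1): two-way model, absolute agreement,
#' single rating
#'
#' Computed from the mean squares of the subject-by-rating decomposition:
#' with `MSR` (subjects), `MSC` (ratings) and `MSE` (error),
#' \deqn{ICC(A,1) = \frac{MSR - MSE}{MSR + (k-1) MSE + \frac{k}{n}(MSC - MSE)}.}
#' The 95% CI is the standard F-based interval for the absolute-agreement
#' single-measure coefficient (McGraw & Wong convention).
#'
#' @param pre1,pre2 Paired numeric vectors (the two ratings).
#' @param conf_level Confidence level.
#' @return A one-row tibble: `icc`, `icc_lo`, `icc_hi`, `band`,
#'   `degenerate` (`TRUE` when total variance is zero and the ICC is
#'   undefined; a perfect replication of varying scores returns `icc = 1`).
#' @examples
#' icc_a1(c(1, 3, 5, 7), c(2, 4, 6, 8))
#' @export
icc_a1 <- function(pre1, pre2, conf_level = 0.95) {
  check_paired(pre1, pre2)
  Y <- cbind(pre1, pre2)
  n <- nrow(Y); k <- ncol(Y)
  gm <- mean(Y)
  if (all(Y == gm)) {
    return(tibble::tibble(icc = NA_real_, icc_lo = NA_real_,
                          icc_hi = NA_real_, band = NA_character_,
                          degenerate = TRUE))
  }
  ssr <- k * sum((rowMeans(Y) - gm)^2)
  ssc <- n * sum((colMeans(Y) - gm)^2)
  sse <- sum((Y - gm)^2) - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))

  alpha <- 1 - conf_level
  if (mse == 0 && msc == 0) {
    lo <- hi <- 1
  } else {
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    if (!is.finite(a) || !is.finite(b)) {
      lo <- hi <- 1
    } else {
      v <- (a * msc + b * mse)^2 /
        ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
      f_l <- qf(1 - alpha / 2, n - 1, v)
      f_u <- qf(1 - alpha / 2, v, n - 1)
      lo <- n * (msr - f_l * mse) /
        (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
      hi <- n * (f_u * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    }
  }
  tibble::tibble(icc = icc, icc_lo = lo, icc_hi = hi,
                 band = icc_band(icc), degenerate = FALSE)
}

#' Standard error of measurement and minimal detectable change
#'
#' `SEM = SD * sqrt(1 - ICC)` where `SD` is the standard deviation of all
#' scores from both baseline trials pooled; `MDC = SEM * 1.96 * sqrt(2)`.
#' The relative versions divide by the grand mean `M` of all scores.
#'
#' @param sd_all Pooled SD of all Pre1 and Pre2 scores (>= 0).
#' @param icc Intraclass correlation in `[0, 1]`.
#' @param grand_mean Grand mean `M` of all Pre1 and Pre2 scores (non-zero
#'   for the percentage versions).
#' @return A one-row tibble: `sem`, `sem_pct`, `mdc`, `mdc_pct`.
#' @examples
#' sem_mdc(sd_all = 2.31, icc = 0.88, grand_mean = 21.685)
#' @export
sem_mdc <- function(sd_all, icc, grand_mean = NA_real_) {
  if (is.na(icc) || icc < 0 || icc > 1) {
    abort("`icc` must lie in [0, 1].", class = "tmg_domain_error")
  }
  if (sd_all < 0) {
    abort("`sd_all` must be non-negative.", class = "tmg_domain_error")
  }
  sem <- sd_all * sqrt(1 - icc)
  mdc <- sem * 1.96 * sqrt(2)
  tibble::tibble(
    sem = sem,
    sem_pct = 100 * sem / grand_mean,
    mdc = mdc,
    mdc_pct = 100 * mdc / grand_mean)
}

#' Test--retest reliability table for repeated baseline twitches
#'
#' For every parameter, compares the two baseline trials: systematic bias
#' (paired t-test), bias-corrected effect size, ICC(A,1), SEM and minimal
#' detectable change, reproducing the full per-parameter reliability chain.
#'
#' @param params Parameter tibble with columns `subject`, `timepoint` and
#'   one numeric column per parameter (e.g. [extract_parameters()] piped
#'   through [add_vc_parameters()]).
#' @param pre1,pre2 Labels of the two baseline timepoints.
#' @param parameters Parameter columns to analyse (default: all numeric).
#' @return A `tmg_reliability` tibble, one row per parameter, with columns
#'   `parameter`, `n`, `mean_pre1`, `sd_pre1`, `mean_pre2`, `sd_pre2`,
#'   `bias`, `bias_lo`, `bias_hi`, `t_stat`, `p_value`, `g`, `g_lo`, `g_hi`,
#'   `g_band`, `icc`, `icc_lo`, `icc_hi`, `icc_band`, `sem`, `sem_pct`,
#'   `mdc`, `mdc_pct`.
#' @export
reliability_table <- function(params, pre1 = "Pre1", pre2 = "Pre2",
                              parameters = NULL) {
  stopifnot(all(c("subject", "timepoint") %in% names(params)))
  if (is.null(parameters)) {
    parameters <- names(params)[vapply(params, is.numeric, logical(1))]
  }
  rows <- purrr::map(parameters, function(p) {
    w <- params %>%
      dplyr::filter(.data$timepoint %in% c(pre1, pre2)) %>%
      dplyr::select("subject", "timepoint", value = dplyr::all_of(p)) %>%
      tidyr::pivot_wider(names_from = "timepoint", values_from = "value") %>%
      dplyr::filter(complete.cases(.))
    x1 <- w[[pre1]]; x2 <- w[[pre2]]
    n <- length(x1)
    all_scores <- c(x1, x2)
    pb <- paired_bias(x1, x2)
    hg <- hedges_g(x1, x2)
    ic <- icc_a1(x1, x2)
    sm <- if (ic$degenerate) {
      tibble::tibble(sem = NA_real_, sem_pct = NA_real_,
                     mdc = NA_real_, mdc_pct = NA_real_)
    } else {
      sem_mdc(sd(all_scores), max(0, min(1, ic$icc)), mean(all_scores))
    }
    tibble::tibble(
      parameter = p, n = n,
      mean_pre1 = mean(x1), sd_pre1 = sd(x1),
      mean_pre2 = mean(x2), sd_pre2 = sd(x2),
      bias = pb$bias, bias_lo = pb$bias_lo, bias_hi = pb$bias_hi,
      t_stat = pb$t_stat, p_value = pb$p_value,
      g = hg$g, g_lo = hg$g_lo, g_hi = hg$g_hi, g_band = hg$band,
      icc = ic$icc, icc_lo = ic$icc_lo, icc_hi = ic$icc_hi,
      icc_band = ic$band,
      sem = sm$sem, sem_pct = sm$sem_pct, mdc = sm$mdc, mdc_pct = sm$mdc_pct)
  }) %>% dplyr::bind_rows()
  class(rows) <- c("tmg_reliability", class(rows))
  rows
}

check_paired <- function(pre1, pre2) {
  if (length(pre1) != length(pre2)) {
    abort("Paired vectors must have equal length.", class = "tmg_pairing_error")
  }
  if (length(pre1) < 2) {
    abort("At least two pairs are required.", class = "tmg_pairing_error")
  }
  invisible(TRUE)
}
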