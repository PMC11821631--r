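#' Classify a change from baseline against the minimal detectable change
#'
#' A subject is `potentiated` when the change from baseline strictly exceeds
#' the MDC, `fatigued` when the decrease strictly exceeds it, and
#' `unchanged` otherwise (a change exactly equal to the MDC does not exceed
#' it).
#'
#' @param delta Change from baseline, in parameter units (vectorised).
#' @param mdc Minimal detectable change in the same units (>= 0).
#' @return Factor with levels `potentiated`, `unchanged`, `fatigued`; `NA`
#'   deltas give `NA`.
#' @examples
#' classify_change(c(5, -5, 1), mdc = 1.38)
#' @export
classify_change <- function(delta, mdc) {
  if (any(mdc < 0, na.rm = TRUE)) {
    abort("`mdc` must be non-negative.", class = "tmg_domain_error")
  }
  out <- ifelse(delta > mdc, "potentiated",
                ifelse(delta < -mdc, "fatigued", "unchanged"))
  factor(out, levels = c("potentiated", "unchanged", "fatigued"))
}

#' Cross-tabulate index-test against reference-test classifications
#'
#' Builds the 2 x 2 contingency table for one condition (`potentiated` or
#' `fatigued`): a subject is condition-positive when its status equals the
#' condition. The reference test (peak twitch torque) defines the columns,
#' the index test (a TMG displacement parameter) the rows.
#'
#' @param reference,index Status factors/characters of equal length (as from
#'   [classify_change()]).
#' @param condition `"potentiated"` or `"fatigued"`.
#' @return A `tmg_contingency` object (list with `tp`, `fp`, `fn`, `tn`,
#'   `condition`).
#' @export
build_contingency <- function(reference, index,
                              condition = c("potentiated", "fatigued")) {
  condition <- match.arg(condition)
  if (length(reference) != length(index)) {
    abort("`reference` and `index` must have equal length.",
          class = "tmg_pairing_error")
  }
  ok <- !is.na(reference) & !is.na(index)
  ref_pos <- as.character(reference[ok]) == condition
  ind_pos <- as.character(index[ok]) == condition
  structure(
    list(tp = sum(ind_pos & ref_pos), fp = sum(ind_pos & !ref_pos),
         fn = sum(!ind_pos & ref_pos), tn = sum(!ind_pos & !ref_pos),
         condition = condition),
    class = "tmg_contingency")
}

#' @rdname build_contingency
#' @param tp,fp,fn,tn Non-negative counts.
#' @export
contingency_table <- function(tp, fp, fn, tn,
                              condition = c("potentiated", "fatigued")) {
  condition <- match.arg(condition)
  counts <- c(tp, fp, fn, tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Counts must be non-negative integers.", class = "tmg_domain_error")
  }
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, condition = condition),
            class = "tmg_contingency")
}

#' @export
print.tmg_contingency <- function(x, ...) {
  cat(sprintf("<tmg_contingency> condition: %s\n", x$condition))
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(index = c("positive", "negative"),
                              reference = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Exact binomial (Clopper--Pearson) confidence interval
#'
#' Beta-quantile formulation of the exact interval for a binomial
#' proportion: the lower bound is 0 when there are no successes and the
#' upper bound is 1 when every trial succeeded.
#'
#' @param successes,trials Counts with `0 <= successes <= trials`,
#'   `trials >= 1`.
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble: `estimate`, `lower`, `upper`.
#' @examples
#' clopper_pearson(16, 16)
#' clopper_pearson(1, 14)
#' @export
clopper_pearson <- function(successes, trials, conf_level = 0.95) {
  if (trials < 1 || successes < 0 || successes > trials) {
    abort("Need 0 <= successes <= trials and trials >= 1.",
          class = "tmg_domain_error")
  }
  alpha <- 1 - conf_level
  lower <- if (successes == 0) 0 else
    qbeta(alpha / 2, successes, trials - successes + 1)
  upper <- if (successes == trials) 1 else
    qbeta(1 - alpha / 2, successes + 1, trials - successes)
  tibble::tibble(estimate = successes / trials, lower = lower, upper = upper)
}

#' Diagnostic accuracy metrics from a contingency table
#'
#' Sensitivity `tp / (tp + fn)`, specificity `tn / (fp + tn)`, positive and
#' negative predictive values, diagnostic effectiveness
#' `DE = Sn * prevalence + Sp * (1 - prevalence)` (algebraically the overall
#' proportion of correct classifications `(tp + tn) / total`, which is also
#' how it is computed when an empty margin leaves Sn or Sp undefined), and
#' Youden's index `YI = Sn + Sp - 1`. Each proportion carries an exact
#' Clopper--Pearson interval; the Youden interval combines the Sn and Sp
#' interval endpoints. A ratio with an empty denominator is `NA` (flagged
#' undefined), never silently 0.
#'
#' @param table A `tmg_contingency` from [build_contingency()] or
#'   [contingency_table()].
#' @param conf_level Confidence level for the intervals.
#' @return A one-row tibble with `sn`, `sp`, `ppv`, `npv`, `de`, `yi`, their
#'   interval bounds (`*_lo`, `*_hi`), `prevalence` and `n`.
#' @examples
#' accuracy_metrics(contingency_table(tp = 1, fp = 0, fn = 13, tn = 2,
#'                                    condition = "fatigued"))
#' @export
accuracy_metrics <- function(table, conf_level = 0.95) {
  stopifnot(inherits(table, "tmg_contingency"))
  tp <- table$tp; fp <- table$fp; fn <- table$fn; tn <- table$tn
  total <- tp + fp + fn + tn
  if (total < 1) abort("Empty contingency table.", class = "tmg_domain_error")

  prop_ci <- function(x, n) {
    if (n == 0) {
      return(tibble::tibble(estimate = NA_real_, lower = NA_real_,
                            upper = NA_real_))
    }
    clopper_pearson(x, n, conf_level)
  }
  sn_ci <- prop_ci(tp, tp + fn)
  sp_ci <- prop_ci(tn, fp + tn)
  ppv_ci <- prop_ci(tp, tp + fp)
  npv_ci <- prop_ci(tn, fn + tn)
  de_ci <- prop_ci(tp + tn, total)
  yi_ci <- if (is.na(sn_ci$estimate) || is.na(sp_ci$estimate)) {
    tibble::tibble(estimate = NA_real_, lower = NA_real_, upper = NA_real_)
  } else {
    tibble::tibble(estimate = sn_ci$estimate + sp_ci$estimate - 1,
                   lower = sn_ci$lower + sp_ci$lower - 1,
                   upper = sn_ci$upper + sp_ci$upper - 1)
  }
  tibble::tibble(
    sn = sn_ci$estimate, sn_lo = sn_ci$lower, sn_hi = sn_ci$upper,
    sp = sp_ci$estimate, sp_lo = sp_ci$lower, sp_hi = sp_ci$upper,
    ppv = ppv_ci$estimate, ppv_lo = ppv_ci$lower, ppv_hi = ppv_ci$upper,
    npv = npv_ci$estimate, npv_lo = npv_ci$lower, npv_hi = npv_ci$upper,
    de = de_ci$estimate, de_lo = de_ci$lower, de_hi = de_ci$upper,
    yi = yi_ci$estimate, yi_lo = yi_ci$lower, yi_hi = yi_ci$upper,
    prevalence = (tp + fn) / total, n = total)
}

#' Rank-based AUROC
#'
#' The area under the ROC curve computed as the probability that a randomly
#' chosen condition-positive subject has a higher score than a randomly
#' chosen negative subject, with ties counting one half (the Mann--Whitney
#' formulation). Scores must be oriented so that larger values indicate the
#' condition; for a fatigue condition scored by percent change, pass
#' `direction = "decrease"` to negate the scores.
#'
#' Accuracy bands: < 0.5 insufficient, then bad, sufficient, good,
#' very good and excellent at 0.5, 0.6, 0.7, 0.8 and 0.9.
#'
#' @param scores Continuous per-subject scores (e.g. percent change from
#'   baseline).
#' @param labels Reference statuses; positives are those equal to
#'   `positive`.
#' @param positive Label counting as condition-positive.
#' @param direction `"increase"` if larger scores indicate the condition,
#'   `"decrease"` if smaller scores do.
#' @return A one-row tibble: `auroc`, `band`, `n_pos`, `n_neg`,
#'   `undefined` (`TRUE` when either class is absent).
#' @examples
#' roc_auc(c(3, 2, 1, 0), c("f", "f", "n", "n"), positive = "f")
#' @export
roc_auc <- function(scores, labels, positive,
                    direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  if (direction == "decrease") scores <- -scores
  pos <- as.character(labels) == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    return(tibble::tibble(auroc = NA_real_, band = NA_character_,
                          n_pos = n1, n_neg = n0, undefined = TRUE))
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  tibble::tibble(auroc = auc, band = auroc_band(auc),
                 n_pos = n1, n_neg = n0, undefined = FALSE)
}

#' @rdname effect_band
#' @param auroc AUROC values (vectorised).
#' @export
auroc_band <- function(auroc) {
  cut(auroc, breaks = c(-Inf, 0.5, 0.6, 0.7, 0.8, 0.9, Inf),
      labels = c("insufficient", "bad", "sufficient", "good", "very good",
                 "excellent"),
      right = FALSE) %>% as.character()
}

#' Diagnostic accuracy of TMG parameters against peak twitch torque
#'
#' For each requested timepoint and each index parameter, classifies every
#' subject by the change from baseline against the parameter's MDC
#' ([classify_change()]), cross-tabulates the classification against the
#' reference classification from peak twitch torque, and computes the full
#' set of accuracy metrics plus the rank-based AUROC of the index
#' parameter's percent change. `Set*` timepoints assess the `potentiated`
#' condition, `Post*` timepoints the `fatigued` condition.
#'
#' The same increase/decrease rule is applied to every parameter, including
#' the timing parameters whose physiological response to potentiation is a
#' decrease; pass `direction_map` to invert selected parameters instead.
#'
#' @param params Wide parameter tibble (`subject`, `timepoint`, one column
#'   per parameter).
#' @param mdc Named numeric vector of MDCs per parameter, or a
#'   [reliability_table()] result from which they are taken.
#' @param baseline Baseline timepoint label.
#' @param timepoints Timepoints to assess (default `Set1`, `Post1`,
#'   `Post15`).
#' @param reference Name of the reference parameter (default `"Pt"`).
#' @param direction_map Optional named character vector mapping parameters
#'   to `"increase"`/`"decrease"`, inverting the classification direction
#'   for those parameters. Off by default.
#' @return A `tmg_diagnostics` tibble, one row per (timepoint, parameter),
#'   with the condition, the contingency counts, all accuracy metrics with
#'   CIs, and AUROC with its band.
#' @export
diagnostic_table <- function(params, mdc, baseline = "Pre2",
                             timepoints = c("Set1", "Post1", "Post15"),
                             reference = "Pt", direction_map = NULL) {
  if (inherits(mdc, "tmg_reliability")) {
    mdc <- stats::setNames(mdc$mdc, mdc$parameter)
  }
  pc <- percent_change_table(params, baseline = baseline,
                             parameters = intersect(names(mdc), names(params)))
  index_pars <- setdiff(intersect(names(mdc), unique(pc$parameter)),
                        reference)
  purrr::map(timepoints, function(tp) {
    condition <- if (grepl("^Set", tp)) "potentiated" else "fatigued"
    at_tp <- pc %>% dplyr::filter(.data$timepoint == tp)
    ref <- at_tp %>% dplyr::filter(.data$parameter == reference)
    ref_status <- classify_change(ref$delta, mdc[[reference]])
    names(ref_status) <- ref$subject
    purrr::map(index_pars, function(p) {
      idx <- at_tp %>% dplyr::filter(.data$parameter == p)
      delta <- idx$delta
      if (!is.null(direction_map) && identical(direction_map[[p]],
                                               "decrease")) {
        delta <- -delta
      }
      idx_status <- classify_change(delta, mdc[[p]])
      tab <- build_contingency(ref_status[idx$subject], idx_status,
                               condition)
      am <- accuracy_metrics(tab)
      ra <- roc_auc(idx$pct_change, ref_status[idx$subject],
                    positive = condition,
                    direction = if (condition == "fatigued") "decrease"
                                else "increase")
      dplyr::bind_cols(
        tibble::tibble(timepoint = tp, parameter = p, condition = condition,
                       tp_count = tab$tp, fp_count = tab$fp,
                       fn_count = tab$fn, tn_count = tab$tn),
        am,
        tibble::tibble(auroc = ra$auroc, auroc_band = ra$band))
    }) %>% dplyr::bind_rows()
  }) %>% dplyr::bind_rows() -> out
  class(out) <- c("tmg_diagnostics", class(out))
  out
}
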