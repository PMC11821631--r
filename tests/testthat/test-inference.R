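test_that("Tukey 3xIQR fences flag only extreme points", {
  expect_equal(flag_extremes(c(1, 2, 3, 4, 5)), rep(FALSE, 5))
  f <- flag_extremes(c(1, 2, 3, 4, 100))
  expect_equal(which(f), 5L)
  # hand-computed: Q1 = 2, Q3 = 4 (type-7), fences [-4, 10]
  expect_equal(flag_extremes(c(1, 2, 3, 4, 100)),
               c(1, 2, 3, 4, 100) < -4 | c(1, 2, 3, 4, 100) > 10)
  expect_equal(flag_extremes(rep(7, 6)), rep(FALSE, 6))
})

test_that("interior missing values are filled from nearest neighbours", {
  expect_equal(interpolate_missing(c(1, NA, 3)), c(1, 2, 3))
  expect_equal(interpolate_missing(c(2, NA, NA, 8)), c(2, 5, 5, 8))
  expect_equal(interpolate_missing(c(1, 2, 3)), c(1, 2, 3))
  expect_error(interpolate_missing(c(NA, 2, 3)),
               class = "tmg_unresolvable_missing")
  expect_error(interpolate_missing(c(1, 2, NA)),
               class = "tmg_unresolvable_missing")
})

test_that("with two timepoints the RM-ANOVA F equals the paired t squared", {
  set.seed(7)
  d <- tidyr::expand_grid(subject = sprintf("s%d", 1:10),
                          timepoint = c("A", "B"))
  d$value <- rnorm(nrow(d), mean = ifelse(d$timepoint == "B", 1, 0))
  fit <- rm_anova(d, value, subject, timepoint)
  wide <- tidyr::pivot_wider(d, names_from = timepoint,
                             values_from = value)
  tt <- t.test(wide$A, wide$B, paired = TRUE)
  expect_equal(fit$f_stat, unname(tt$statistic)^2, tolerance = 1e-8)
  expect_equal(fit$epsilon, 1)
  expect_equal(fit$p_value, tt$p.value, tolerance = 1e-8)
})

test_that("RM-ANOVA removes subject effects and detects strong time effects", {
  set.seed(17)
  n <- 12; k <- 5
  d <- tidyr::expand_grid(subject = sprintf("s%02d", 1:n),
                          timepoint = sprintf("t%d", 1:k))
  d$value <- rnorm(nrow(d))
  f1 <- rm_anova(d, value, subject, timepoint)
  d2 <- d
  shift <- stats::setNames(rnorm(n, sd = 50), sprintf("s%02d", 1:n))
  d2$value <- d2$value + shift[d2$subject]
  f2 <- rm_anova(d2, value, subject, timepoint)
  expect_equal(f1$f_stat, f2$f_stat, tolerance = 1e-8)

  d3 <- d
  d3$value <- d3$value + ifelse(d3$timepoint %in% c("t4", "t5"), 4, 0)
  f3 <- rm_anova(d3, value, subject, timepoint)
  expect_lt(f3$p_value, 0.001)
  expect_gt(f3$partial_eta_sq, 0.5)
})

test_that("sphericity epsilon respects its theoretical bounds", {
  set.seed(27)
  for (i in 1:10) {
    n <- sample(6:20, 1)
    k <- sample(3:8, 1)
    Y <- matrix(rnorm(n * k), n, k)
    eps <- tmgtwitch:::gg_epsilon(Y)
    expect_gte(eps, 1 / (k - 1) - 1e-12)
    expect_lte(eps, 1 + 1e-12)
    d <- tibble::tibble(subject = rep(seq_len(n), k),
                        timepoint = rep(seq_len(k), each = n),
                        value = as.vector(Y))
    fit_gg <- rm_anova(d, value, subject, timepoint,
                       correction = "greenhouse-geisser")
    fit_un <- rm_anova(d, value, subject, timepoint, correction = "none")
    expect_lte(fit_gg$df_num, fit_un$df_num + 1e-12)
    expect_lte(fit_gg$df_den, fit_un$df_den + 1e-12)
  }
})

test_that("incomplete matrices are rejected with guidance", {
  d <- tidyr::expand_grid(subject = c("a", "b", "c"),
                          timepoint = c("t1", "t2", "t3"))
  d$value <- rnorm(nrow(d))
  d$value[4] <- NA
  expect_error(rm_anova(d, value, subject, timepoint),
               class = "tmg_incomplete_matrix")
})

test_that("tidy and glance summarise the fit", {
  set.seed(37)
  d <- tidyr::expand_grid(subject = sprintf("s%d", 1:8),
                          timepoint = sprintf("t%d", 1:4))
  d$value <- rnorm(nrow(d))
  fit <- rm_anova(d, value, subject, timepoint)
  td <- tidy(fit)
  gl <- glance(fit)
  expect_equal(td$statistic, fit$f_stat)
  expect_equal(gl$p.value, fit$p_value)
  expect_equal(gl$n_subjects, 8)
})

test_that("Bonferroni post hocs against baseline behave as expected", {
  base_vals <- c(10, 12, 14, 16, 18, 20)
  d <- tidyr::expand_grid(subject = sprintf("s%d", 1:6),
                          timepoint = factor(c("Pre2", "Set1", "Post1"),
                                             levels = c("Pre2", "Set1",
                                                        "Post1")))
  d <- dplyr::arrange(d, timepoint, subject)
  d$value <- rep(base_vals, 3)
  ph <- bonferroni_vs_baseline(d, value, subject, timepoint,
                               baseline = "Pre2")
  expect_equal(ph$p_adj, c(1, 1))
  expect_equal(ph$g, c(0, 0))

  # raw p multiplied by the family size, capped at 1
  expect_equal(min(1, 0.01 * 15), 0.15)
  d2 <- d
  set.seed(47)
  d2$value <- d2$value + rnorm(nrow(d2), sd = 0.2) +
    ifelse(d2$timepoint == "Set1", 30, 0)
  ph2 <- bonferroni_vs_baseline(d2, value, subject, timepoint,
                                baseline = "Pre2")
  expect_lt(ph2$p_adj[ph2$timepoint == "Set1"], 0.05)
  expect_gt(ph2$p_adj[ph2$timepoint == "Post1"], 0.05)
  expect_true(all(ph2$p_adj >= ph2$p_raw))
})

test_that("Pearson association reports r, p and the magnitude band", {
  x <- c(1, 2, 3, 4, 5)
  pa <- pearson_assoc(x, 2 * x + 1)
  expect_equal(pa$r, 1)
  expect_equal(pa$band, "extremely large")
  expect_equal(pa$p_value, 0)

  set.seed(57)
  pa2 <- pearson_assoc(rnorm(500), rnorm(500))
  expect_lt(abs(pa2$r), 0.12)

  expect_equal(correlation_band(0.55), "large")
  expect_true(pearson_assoc(rep(1, 5), rnorm(5))$degenerate)
  expect_error(pearson_assoc(1:3, 1:4), class = "tmg_pairing_error")
})
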