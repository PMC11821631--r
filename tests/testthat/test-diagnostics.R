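test_that("MDC classification requires strict exceedance", {
  expect_equal(as.character(classify_change(0, 2)), "unchanged")
  expect_equal(as.character(classify_change(2, 2)), "unchanged")
  expect_equal(as.character(classify_change(-2, 2)), "unchanged")
  expect_equal(as.character(classify_change(5, 1.38)), "potentiated")
  expect_equal(as.character(classify_change(-5, 1.38)), "fatigued")
  expect_true(is.na(classify_change(NA_real_, 1)))
  expect_error(classify_change(1, -0.5), class = "tmg_domain_error")
})

test_that("contingency tables cross-tabulate reference vs index status", {
  all_pos <- rep("potentiated", 16)
  tab <- build_contingency(all_pos, all_pos, "potentiated")
  expect_equal(tab$tp, 16)
  expect_equal(tab$fp + tab$fn + tab$tn, 0)

  ref <- c("fatigued", "fatigued", "unchanged", "unchanged")
  idx <- c("unchanged", "unchanged", "fatigued", "fatigued")
  tab2 <- build_contingency(ref, idx, "fatigued")
  expect_equal(tab2$tp, 0)
  expect_equal(tab2$tn, 0)
  expect_equal(tab2$fp, 2)
  expect_equal(tab2$fn, 2)

  # 6-subject fixture counted by hand
  ref3 <- c("fatigued", "fatigued", "fatigued", "unchanged", "unchanged",
            "potentiated")
  idx3 <- c("fatigued", "unchanged", "fatigued", "fatigued", "unchanged",
            "unchanged")
  tab3 <- build_contingency(ref3, idx3, "fatigued")
  expect_equal(unlist(tab3[c("tp", "fp", "fn", "tn")]),
               c(tp = 2, fp = 1, fn = 1, tn = 2))
  expect_error(build_contingency(ref3, idx3[1:3], "fatigued"),
               class = "tmg_pairing_error")
})

test_that("accuracy metrics reproduce the published contingency rows", {
  # post-exercise contraction-time row: 1 true positive of 14 fatigued,
  # 2 true negatives of 2
  t_tc <- contingency_table(tp = 1, fp = 0, fn = 13, tn = 2,
                            condition = "fatigued")
  m <- accuracy_metrics(t_tc)
  expect_equal(m$sn, 1 / 14, tolerance = 1e-12)
  expect_equal(round(m$sn, 2), 0.07)
  expect_equal(m$sp, 1)
  expect_equal(round(m$de, 2), 0.19)

  # post-exercise displacement-amplitude row
  t_dm <- contingency_table(tp = 5, fp = 1, fn = 9, tn = 1,
                            condition = "fatigued")
  m2 <- accuracy_metrics(t_dm)
  expect_equal(round(m2$ppv, 2), 0.83)
  expect_equal(m2$npv, 0.10)
  expect_equal(round(m2$yi, 2), -0.14)
  expect_equal(round(m2$de, 2), 0.38)

  perfect <- accuracy_metrics(contingency_table(5, 0, 0, 5))
  expect_equal(perfect$sn, 1)
  expect_equal(perfect$sp, 1)
  expect_equal(perfect$ppv, 1)
  expect_equal(perfect$npv, 1)
  expect_equal(perfect$de, 1)
  expect_equal(perfect$yi, 1)
})

test_that("undefined margins are flagged NA and DE falls back to accuracy", {
  # every reference subject positive: specificity/PPV margins empty or full
  t_all <- contingency_table(tp = 16, fp = 0, fn = 0, tn = 0)
  m <- accuracy_metrics(t_all)
  expect_equal(m$sn, 1)
  expect_true(is.na(m$sp))
  expect_true(is.na(m$yi))
  expect_equal(m$de, 1)  # reduces to sensitivity when prevalence is 1
  expect_equal(m$prevalence, 1)
})

test_that("DE equals overall accuracy on random tables", {
  set.seed(67)
  for (i in 1:25) {
    cnt <- as.list(sample(0:10, 4, replace = TRUE))
    names(cnt) <- c("tp", "fp", "fn", "tn")
    if (Reduce(`+`, cnt) == 0) next
    m <- accuracy_metrics(do.call(contingency_table, cnt))
    acc <- (cnt$tp + cnt$tn) / Reduce(`+`, cnt)
    expect_equal(m$de, acc, tolerance = 1e-12)
    if (!is.na(m$sn) && !is.na(m$sp)) {
      prev <- m$prevalence
      expect_equal(m$sn * prev + m$sp * (1 - prev), m$de, tolerance = 1e-12)
      expect_equal(m$yi, m$sn + m$sp - 1, tolerance = 1e-12)
    }
  }
})

test_that("Clopper-Pearson intervals match published bounds and properties", {
  cp16 <- clopper_pearson(16, 16)
  expect_equal(cp16$upper, 1)
  expect_equal(round(cp16$lower, 2), 0.79)

  cp1 <- clopper_pearson(1, 14)
  expect_equal(round(cp1$estimate, 2), 0.07)
  expect_equal(round(cp1$upper, 2), 0.34)
  expect_lt(cp1$lower, 0.01)

  expect_equal(clopper_pearson(0, 10)$lower, 0)
  expect_equal(clopper_pearson(10, 10)$upper, 1)

  set.seed(77)
  for (i in 1:20) {
    n <- sample(5:100, 1)
    x <- sample(0:n, 1)
    ci <- clopper_pearson(x, n)
    expect_lte(ci$lower, x / n)
    expect_gte(ci$upper, x / n)
  }
  # width shrinks with more trials at a fixed proportion
  widths <- vapply(c(10, 40, 160, 640), function(n) {
    ci <- clopper_pearson(round(0.3 * n), n)
    ci$upper - ci$lower
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_error(clopper_pearson(5, 4), class = "tmg_domain_error")
})

test_that("rank-based AUROC matches the exhaustive pairwise oracle", {
  r1 <- roc_auc(c(4, 3, 2, 1), c("f", "f", "n", "n"), positive = "f")
  expect_equal(r1$auroc, 1)
  expect_equal(r1$band, "excellent")

  r2 <- roc_auc(rep(1, 8), rep(c("f", "n"), 4), positive = "f")
  expect_equal(r2$auroc, 0.5)
  expect_equal(r2$band, "bad")

  set.seed(87)
  for (i in 1:10) {
    scores <- round(rnorm(16), 1)  # rounding forces some ties
    labels <- rep(c("pos", "neg"), each = 8)
    r <- roc_auc(scores, labels, positive = "pos")
    expect_equal(r$auroc, oracle_auc(scores, labels == "pos"),
                 tolerance = 1e-12)
  }

  r3 <- roc_auc(c(1, 2, 3), rep("pos", 3), positive = "pos")
  expect_true(r3$undefined)

  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(88)
    sc <- rnorm(30)
    lb <- sample(c("a", "b"), 30, replace = TRUE, prob = c(0.4, 0.6))
    ours <- roc_auc(sc, lb, positive = "a")$auroc
    theirs <- as.numeric(pROC::auc(pROC::roc(
      response = lb, predictor = sc, levels = c("b", "a"),
      direction = "<", quiet = TRUE)))
    expect_equal(ours, theirs, tolerance = 1e-12)
  }

  # decreasing scores indicate the condition when direction = "decrease"
  r4 <- roc_auc(c(-30, -20, 5, 10), c("f", "f", "n", "n"),
                positive = "f", direction = "decrease")
  expect_equal(r4$auroc, 1)
})

test_that("AUROC bands follow the interpretation thresholds", {
  expect_equal(auroc_band(c(0.45, 0.55, 0.65, 0.75, 0.85, 0.95)),
               c("insufficient", "bad", "sufficient", "good", "very good",
                 "excellent"))
})

test_that("full coupling makes amplitude-derived TMG classifications agree with torque", {
  cfg <- sim_config(n_subjects = 12, displacement_coupling = 1,
                    within_subject_sd = 0.01, seed = 97)
  p <- extract_parameters(simulate_cohort(cfg)) %>% add_vc_parameters()
  rel <- reliability_table(p, parameters = c("Pt", "Dm", "Vc0_10",
                                             "Vc0_90", "Vc10_90"))
  dg <- diagnostic_table(p, rel)
  amp_pars <- c("Dm", "Vc0_10", "Vc0_90", "Vc10_90")
  agree <- dg %>%
    dplyr::filter(.data$parameter %in% amp_pars) %>%
    dplyr::summarise(acc = sum(.data$tp_count + .data$tn_count) /
                       sum(.data$n))
  expect_gte(agree$acc, 0.95)
})

test_that("decoupled displacement drives post-exercise sensitivity to zero", {
  cfg <- sim_config(n_subjects = 12, displacement_coupling = 0,
                    within_subject_sd = 0.01, seed = 97)
  p <- extract_parameters(simulate_cohort(cfg)) %>% add_vc_parameters()
  rel <- reliability_table(p, parameters = c("Pt", "Dm"))
  dg <- diagnostic_table(p, rel, timepoints = "Post1")
  dm_row <- dg[dg$parameter == "Dm", ]
  expect_lte(dm_row$sn, 0.2)
})
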