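test_that("make_confusion cross-tabulates score >= threshold against death", {
  expect_equal(
    make_confusion(c(100, 200), c(FALSE, TRUE), 145),
    tibble::tibble(threshold = 145, tp = 1L, fp = 0L, fn = 0L, tn = 1L)
  )
  expect_equal(
    unlist(make_confusion(150, FALSE, 145)[, c("tp", "fp", "fn", "tn")]),
    c(tp = 0L, fp = 1L, fn = 0L, tn = 0L)
  )
  # threshold at or below the minimum score: nobody is negative
  cm <- make_confusion(c(10, 50, 90), c(TRUE, FALSE, TRUE), 10)
  expect_equal(cm$fn + cm$tn, 0L)
  expect_error(make_confusion(numeric(), logical(), 5),
               class = "nepscore_validation_error")
  expect_error(make_confusion(1:3, c(TRUE, FALSE), 2),
               class = "nepscore_validation_error")
})

test_that("diagnostics reproduce the reconstructed published tables", {
  # unique integer table behind the NEP-T >= 145 report (n=27, 12 deaths,
  # 80% / 23.5% dead by group); uniqueness established in the
  # reconstruction test below
  d <- diagnostics(8, 2, 4, 13)
  expect_equal(as_percent(d$sensitivity), 66.7)
  expect_equal(as_percent(d$specificity), 86.7)
  expect_equal(as_percent(d$ppv), 80.0)
  expect_equal(as_percent(d$npv), 76.5)
  expect_equal(as_percent(d$accuracy), 77.8)
  # same reconstruction for NEP-D >= 116 (70% / 29.5% dead by group)
  d2 <- diagnostics(7, 3, 5, 12)
  expect_equal(as_percent(d2$sensitivity), 58.3)
  expect_equal(as_percent(d2$specificity), 80.0)
  expect_equal(as_percent(d2$ppv), 70.0)
  expect_equal(as_percent(d2$npv), 70.6)
  expect_equal(as_percent(d2$accuracy), 70.4)
})

test_that("diagnostics handle perfect classifiers and zero denominators", {
  perfect <- diagnostics(5, 0, 0, 9)
  expect_equal(
    unlist(perfect[, c("sensitivity", "specificity", "ppv", "npv",
                       "accuracy")]),
    c(sensitivity = 1, specificity = 1, ppv = 1, npv = 1, accuracy = 1)
  )
  expect_equal(perfect$youden_j, 1)
  # nobody positive: sensitivity defined (0), ppv undefined
  none_pos <- diagnostics(0, 0, 3, 4)
  expect_true(is.na(none_pos$ppv))
  expect_equal(none_pos$sensitivity, 0)
  # nobody dead: sensitivity undefined, specificity defined
  none_dead <- diagnostics(0, 2, 0, 5)
  expect_true(is.na(none_dead$sensitivity))
  expect_true(is.na(none_dead$youden_j))
  expect_error(diagnostics(-1, 0, 0, 1), class = "nepscore_validation_error")
})

test_that("diagnostics agree with brute-force recounts on random cohorts", {
  set.seed(101)
  cases <- 0
  while (cases < 1000) {
    n <- sample(5:40, 1)
    xo <- random_score_outcome(n)
    t <- sample(c(xo$scores, sample(0:378, 3)), 1)
    cm <- make_confusion(xo$scores, xo$dead, t)
    # independent recount: explicit per-patient loop
    tp <- fp <- fn <- tn <- 0
    for (i in seq_len(n)) {
      pos <- xo$scores[i] >= t
      if (pos && xo$dead[i]) tp <- tp + 1
      else if (pos) fp <- fp + 1
      else if (xo$dead[i]) fn <- fn + 1
      else tn <- tn + 1
    }
    expect_equal(unlist(cm[, c("tp", "fp", "fn", "tn")]),
                 c(tp = tp, fp = fp, fn = fn, tn = tn),
                 ignore_attr = TRUE)
    d <- diagnostics(cm)
    if (tp + fn > 0) expect_equal(d$sensitivity, tp / (tp + fn))
    if (tn + fp > 0) expect_equal(d$specificity, tn / (tn + fp))
    expect_equal(d$accuracy, (tp + tn) / n)
    cases <- cases + 1
  }
})

test_that("sensitivity falls and specificity rises as the threshold increases", {
  set.seed(7)
  for (rep in 1:20) {
    xo <- random_score_outcome(30)
    if (length(unique(xo$scores)) < 2) next
    if (all(xo$dead) || !any(xo$dead)) xo$dead[1:2] <- c(TRUE, FALSE)
    scan <- tidy(scan_thresholds(
      tibble::tibble(nep_t = xo$scores, vital_status = xo$dead)
    ))
    expect_true(all(diff(scan$sensitivity) <= 1e-12))
    expect_true(all(diff(scan$specificity) >= -1e-12))
    # ppv is at least the prevalence wherever the cutoff beats chance
    prev <- mean(xo$dead)
    informative <- !is.na(scan$youden_j) & scan$youden_j > 0 &
      !is.na(scan$ppv)
    expect_true(all(scan$ppv[informative] >= prev - 1e-12))
  }
})

test_that("threshold scan selects the separating cutoff and honors policies", {
  d <- tibble::tibble(nep_t = c(10, 300), vital_status = c("alive", "dead"))
  scan <- scan_thresholds(d)
  expect_equal(scan$best$threshold, 300)
  expect_equal(scan$best$youden_j, 1)
  # degenerate outcome: scan table returned, no best threshold
  all_dead <- tibble::tibble(nep_t = c(10, 300),
                             vital_status = c("dead", "dead"))
  sc2 <- scan_thresholds(all_dead)
  expect_null(sc2$best)
  expect_true(nrow(tidy(sc2)) >= 2)
  expect_true(is.na(glance(sc2)$threshold))
  expect_error(scan_thresholds(tibble::tibble(nep_t = c(5, 5),
                                              vital_status = c(TRUE, FALSE))),
               class = "nepscore_validation_error")
  # tie-break: prefer the higher-specificity (higher) threshold among equal J
  d3 <- tibble::tibble(nep_t = c(1, 2, 3, 4),
                       vital_status = c(FALSE, FALSE, TRUE, TRUE))
  best <- scan_thresholds(d3)$best
  expect_equal(best$threshold, 3)
  expect_equal(best$youden_j, 1)
  for (pol in c("closest", "accuracy")) {
    expect_equal(scan_thresholds(d3, policy = pol)$best$threshold, 3)
  }
})

test_that("death proportions by group match the published split and chi-square", {
  # cohort realizing the reconstructed NEP-T=145 table: 10 high (8 dead),
  # 17 low (4 dead)
  cohort <- tibble::tibble(
    nep_t = rep(c(200, 100), c(10, 17)),
    vital_status = c(rep("dead", 8), rep("alive", 2),
                     rep("dead", 4), rep("alive", 13))
  )
  out <- proportion_dead_by_group(cohort, 145)
  expect_equal(as_percent(out$p_dead_high), 80.0)
  expect_equal(as_percent(out$p_dead_low), 23.5)
  # hand-computed Pearson statistic on the same 2x2 table
  tab <- matrix(c(13, 2, 4, 8), 2)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(out$chi2, sum((tab - e)^2 / e))
  expect_lt(out$p_value, 0.005)
  expect_lt(out$chi2_yates, out$chi2)
})

test_that("degenerate group splits are reported without a test", {
  all_dead <- tibble::tibble(nep_t = c(100, 200, 300),
                             vital_status = rep("dead", 3))
  out <- proportion_dead_by_group(all_dead, 150)
  expect_equal(out$p_dead_high, 1)
  expect_equal(out$p_dead_low, 1)
  expect_equal(out$chi2, 0)
  expect_equal(out$p_value, 1)
  # one empty group: proportions reported, test not computable
  out2 <- proportion_dead_by_group(
    tibble::tibble(nep_t = c(200, 300), vital_status = c("dead", "alive")),
    100
  )
  expect_equal(out2$n_low, 0)
  expect_true(is.na(out2$p_dead_low))
  expect_true(is.na(out2$chi2))
})

test_that("group mean comparisons behave at the degenerate ends", {
  identical_groups <- tibble::tibble(
    v = rep(c(3, 5, 9), 2),
    g = rep(c("a", "b"), each = 3)
  )
  out <- compare_group_means(identical_groups, "v", group = "g")
  expect_equal(out$t_stat, 0)
  expect_equal(out$p_value, 1)
  # paired NEP-D vs NEP-T on an all-synchronous cohort: zero difference
  cohort <- nep_score(tibble::tibble(
    age_at_diagnosis = c(40, 50, 70),
    primary_site = c("ileum", "pancreas", "ileum"),
    primary_surgery = c(TRUE, FALSE, TRUE),
    functional = c(FALSE, TRUE, FALSE),
    ki67_pct = c(1, 10, 25),
    metastasis_timing = "synchronous"
  ))
  paired <- compare_group_means(cohort, "nep_d", value2 = "nep_t",
                                paired = TRUE)
  expect_equal(paired$mean_a, paired$mean_b)
  expect_equal(paired$t_stat, 0)
  expect_equal(paired$p_value, 1)
  expect_error(
    compare_group_means(tibble::tibble(a = 1:3, b = 1:3), "a",
                        group = NULL, value2 = NULL),
    class = "nepscore_validation_error"
  )
  # n < 2 in a group: not computable
  tiny <- tibble::tibble(v = c(1, 2, 3), g = c("a", "b", "b"))
  expect_true(is.na(compare_group_means(tiny, "v", group = "g")$p_value))
})

test_that("rejection rate under a planted mean shift matches a direct Monte-Carlo estimate", {
  set.seed(2024)
  shift <- 50
  sdev <- 60
  n_a <- 15
  n_b <- 12
  reps <- 600
  via_pkg <- mean(replicate(reps, {
    d <- tibble::tibble(
      v = c(rnorm(n_a, 0, sdev), rnorm(n_b, shift, sdev)),
      g = rep(c("a", "b"), c(n_a, n_b))
    )
    compare_group_means(d, "v", group = "g")$p_value < 0.05
  }))
  direct <- mean(replicate(reps, {
    stats::t.test(rnorm(n_a, 0, sdev), rnorm(n_b, shift, sdev))$p.value < 0.05
  }))
  expect_lt(abs(via_pkg - direct), 0.1)
})

test_that("2x2 reconstruction from printed margins finds each published table uniquely", {
  # NEP-T >= 145: internally consistent, so the minimiser has discrepancy 0
  r1 <- reconstruct_confusion(27, 12, 80, 23.5)
  expect_equal(unlist(r1[1, c("tp", "fp", "fn", "tn")]),
               c(tp = 8, fp = 2, fn = 4, tn = 13), ignore_attr = TRUE)
  expect_equal(r1$discrepancy[1], 0)
  expect_equal(sum(r1$discrepancy == 0), 1)  # uniqueness by exhaustion
  # NEP-D >= 116: printed 29.5% is rounding noise around 5/17 = 29.4%
  r2 <- reconstruct_confusion(27, 12, 70, 29.5)
  expect_equal(unlist(r2[1, c("tp", "fp", "fn", "tn")]),
               c(tp = 7, fp = 3, fn = 5, tn = 12), ignore_attr = TRUE)
  expect_equal(sum(r2$discrepancy == min(r2$discrepancy)), 1)
  # NEP-D >= 90: printed 28.5% vs reconstructed 4/14 = 28.6%
  r3 <- reconstruct_confusion(27, 12, 61.5, 28.5)
  expect_equal(unlist(r3[1, c("tp", "fp", "fn", "tn")]),
               c(tp = 8, fp = 5, fn = 4, tn = 10), ignore_attr = TRUE)
  expect_equal(sum(r3$discrepancy == min(r3$discrepancy)), 1)
  # every candidate table respects the fixed margins
  expect_true(all(r1$tp + r1$fn == 12))
  expect_true(all(r1$tp + r1$fp + r1$fn + r1$tn == 27))
})
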