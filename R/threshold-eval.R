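#' Cross-tabulate a score threshold against vital status
#'
#' "Positive" means score at or above the threshold, and the event is death
#' at the end of follow-up, matching the orientation in which a high
#' prognostic score predicts death. So `tp` counts patients with
#' `score >= threshold` who died, `fp` those who are alive, `fn` deaths
#' below the threshold and `tn` survivors below it.
#'
#' @param scores Numeric vector of scores.
#' @param dead Logical vector (or `"alive"`/`"dead"`) of the same length.
#' @param threshold Numeric cutoff; positives are `score >= threshold`.
#' @return A one-row tibble with columns `threshold`, `tp`, `fp`, `fn`, `tn`.
#' @export
#' @examples
#' make_confusion(c(100, 200), c(FALSE, TRUE), 145)
make_confusion <- function(scores, dead, threshold) {
  dead <- is_dead(dead)
  if (length(scores) == 0 || length(scores) != length(dead)) {
    abort_validation("scores and dead must be nonempty vectors of equal length")
  }
  if (anyNA(scores) || anyNA(dead)) {
    abort_validation("scores and dead must not contain missing values")
  }
  pos <- scores >= threshold
  tibble::tibble(
    threshold = threshold,
    tp = sum(pos & dead), fp = sum(pos & !dead),
    fn = sum(!pos & dead), tn = sum(!pos & !dead)
  )
}

#' Diagnostic accuracy metrics of a 2x2 table
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive and negative
#' predictive values, accuracy `(tp+tn)/n` and Youden's J
#' (`sensitivity + specificity - 1`). A metric whose denominator is zero is
#' reported as `NA` — an explicit "undefined" marker, never a silent `0/0`.
#'
#' @param cm A one-row data frame with columns `tp`, `fp`, `fn`, `tn`
#'   (e.g. from [make_confusion()]), or `tp` given as a scalar together
#'   with `fp`, `fn`, `tn`.
#' @param fp,fn,tn Scalar counts when `cm` is given as the `tp` scalar.
#' @return A one-row tibble with the four counts and columns `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `accuracy`, `youden_j` as proportions in
#'   `[0, 1]`; use [as_percent()] for display.
#' @export
#' @examples
#' diagnostics(make_confusion(c(100, 200, 300), c(FALSE, TRUE, TRUE), 145))
#' diagnostics(8, 2, 4, 13)
diagnostics <- function(cm, fp = NULL, fn = NULL, tn = NULL) {
  if (is.numeric(cm) && length(cm) == 1) {
    cm <- tibble::tibble(tp = cm, fp = fp, fn = fn, tn = tn)
  }
  stopifnot(all(c("tp", "fp", "fn", "tn") %in% names(cm)))
  cm <- tibble::as_tibble(cm)
  if (any(cm$tp < 0 | cm$fp < 0 | cm$fn < 0 | cm$tn < 0)) {
    abort_validation("confusion-matrix cells must be nonnegative")
  }
  n <- cm$tp + cm$fp + cm$fn + cm$tn
  out <- cm
  out$sensitivity <- safe_ratio(cm$tp, cm$tp + cm$fn)
  out$specificity <- safe_ratio(cm$tn, cm$tn + cm$fp)
  out$ppv <- safe_ratio(cm$tp, cm$tp + cm$fp)
  out$npv <- safe_ratio(cm$tn, cm$tn + cm$fn)
  out$accuracy <- safe_ratio(cm$tp + cm$tn, n)
  out$youden_j <- out$sensitivity + out$specificity - 1
  out
}

#' Threshold diagnostics on a cohort table
#'
#' Convenience wrapper: builds the confusion matrix for one threshold from
#' a scored cohort and returns its diagnostic metrics.
#'
#' @param data A scored cohort (see [nep_score()]).
#' @param threshold Numeric cutoff.
#' @param score Name of the score column (`"nep_t"` or `"nep_d"`).
#' @param status Name of the vital-status column.
#' @return A one-row tibble: threshold, counts and metrics.
#' @export
threshold_diagnostics <- function(data, threshold, score = "nep_t",
                                  status = "vital_status") {
  diagnostics(make_confusion(data[[score]], data[[status]], threshold))
}

#' Death proportions above and below a threshold, with a chi-square test
#'
#' Splits the cohort at `score >= threshold`, reports the proportion dead in
#' each group, and tests the 2x2 association with Pearson's chi-square. The
#' uncorrected statistic is the default test; the Yates-corrected version is
#' reported alongside for reference. With an empty group the proportions are
#' still reported and the test columns are `NA` (not computable).
#'
#' @inheritParams threshold_diagnostics
#' @return One-row tibble: `n_high`, `dead_high`, `p_dead_high`, `n_low`,
#'   `dead_low`, `p_dead_low`, `chi2`, `p_value`, `chi2_yates`,
#'   `p_value_yates`.
#' @export
#' @examples
#' cohort <- nep_score(simulate_cohort(sim_config(n = 50), seed = 3))
#' proportion_dead_by_group(cohort, threshold = 145)
proportion_dead_by_group <- function(data, threshold, score = "nep_t",
                                     status = "vital_status") {
  scores <- data[[score]]
  dead <- is_dead(data[[status]])
  if (length(scores) == 0 || length(scores) != length(dead)) {
    abort_validation("score and status columns must be nonempty and aligned")
  }
  high <- scores >= threshold
  out <- tibble::tibble(
    threshold = threshold,
    n_high = sum(high), dead_high = sum(dead[high]),
    p_dead_high = safe_ratio(sum(dead[high]), sum(high)),
    n_low = sum(!high), dead_low = sum(dead[!high]),
    p_dead_low = safe_ratio(sum(dead[!high]), sum(!high)),
    chi2 = NA_real_, p_value = NA_real_,
    chi2_yates = NA_real_, p_value_yates = NA_real_
  )
  if (out$n_high > 0 && out$n_low > 0 &&
      length(unique(dead)) > 1) {
    tab <- table(factor(high, c(FALSE, TRUE)), factor(dead, c(FALSE, TRUE)))
    plain <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    yates <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    out$chi2 <- unname(plain$statistic)
    out$p_value <- plain$p.value
    out$chi2_yates <- unname(yates$statistic)
    out$p_value_yates <- yates$p.value
  } else if (out$n_high > 0 && out$n_low > 0) {
    # all dead or all alive: no association, chi-square degenerates to 0
    out$chi2 <- 0
    out$p_value <- 1
    out$chi2_yates <- 0
    out$p_value_yates <- 1
  }
  out
}

#' Scan all candidate thresholds of a score
#'
#' Evaluates every distinct observed score (plus a `+Inf` sentinel under
#' which nobody is positive) as a cutoff and selects the best one under a
#' policy. The published cutoffs were chosen as "the best compromise between
#' sensitivity and specificity", which is not an algorithm; the default
#' policy here is maximal Youden's J with ties broken by higher specificity
#' and then by lower threshold, and the full scan table is returned so any
#' alternative policy can be audited.
#'
#' @inheritParams threshold_diagnostics
#' @param policy `"youden"` (maximize sensitivity + specificity - 1),
#'   `"closest"` (minimize |sensitivity - specificity|, ties by higher J),
#'   or `"accuracy"` (maximize accuracy, ties by higher J).
#' @return An object of class `nep_scan`: list with `scan` (tibble of
#'   threshold, counts, metrics), `best` (one-row tibble, or `NULL` when the
#'   outcome vector is degenerate), `policy`, `n`, `n_dead`. `tidy()`
#'   returns the scan table, `glance()` the selected row, and `autoplot()`
#'   draws sensitivity/specificity/J against threshold.
#' @export
#' @examples
#' cohort <- nep_score(simulate_cohort(sim_config(n = 40), seed = 7))
#' scan <- scan_thresholds(cohort, score = "nep_t")
#' glance(scan)
scan_thresholds <- function(data, score = "nep_t", status = "vital_status",
                            policy = c("youden", "closest", "accuracy")) {
  policy <- match.arg(policy)
  scores <- data[[score]]
  dead <- is_dead(data[[status]])
  if (length(unique(scores)) < 2) {
    abort_validation("need at least 2 distinct scores to scan thresholds")
  }
  candidates <- c(sort(unique(scores)), Inf)
  scan <- purrr::map_dfr(candidates, function(t) {
    diagnostics(make_confusion(scores, dead, t))
  })
  degenerate <- length(unique(dead)) < 2
  best <- NULL
  if (!degenerate) {
    ranked <- switch(
      policy,
      youden = dplyr::arrange(scan, dplyr::desc(.data$youden_j),
                              dplyr::desc(.data$specificity), .data$threshold),
      closest = dplyr::arrange(scan,
                               abs(.data$sensitivity - .data$specificity),
                               dplyr::desc(.data$youden_j), .data$threshold),
      accuracy = dplyr::arrange(scan, dplyr::desc(.data$accuracy),
                                dplyr::desc(.data$youden_j), .data$threshold)
    )
    best <- ranked[1, ]
  }
  structure(
    list(scan = scan, best = best, policy = policy,
         n = length(scores), n_dead = sum(dead)),
    class = "nep_scan"
  )
}

#' @export
tidy.nep_scan <- function(x, ...) x$scan

#' @export
glance.nep_scan <- function(x, ...) {
  if (is.null(x$best)) {
    return(tibble::tibble(policy = x$policy, n = x$n, n_dead = x$n_dead,
                          threshold = NA_real_, youden_j = NA_real_))
  }
  dplyr::bind_cols(tibble::tibble(policy = x$policy, n = x$n,
                                  n_dead = x$n_dead), x$best)
}

#' @export
print.nep_scan <- function(x, ...) {
  cat(sprintf("Threshold scan over %d candidates (n = %d, %d deaths)\n",
              nrow(x$scan), x$n, x$n_dead))
  if (is.null(x$best)) {
    cat("Outcome vector degenerate: no best threshold defined.\n")
  } else {
    cat(sprintf(
      "Best threshold (%s policy): %s (sens %.1f%%, spec %.1f%%, J = %.3f)\n",
      x$policy, format(x$best$threshold),
      100 * x$best$sensitivity, 100 * x$best$specificity, x$best$youden_j
    ))
  }
  invisible(x)
}

#' @export
autoplot.nep_scan <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::filter(object$scan, is.finite(.data$threshold)),
    cols = c("sensitivity", "specificity", "youden_j"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Score threshold", y = "Metric value", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Compare group means with a t test
#'
#' Means with standard errors and a two-sided t test. Unpaired comparisons
#' default to the Welch test (alive-vs-dead groups of unequal size cannot be
#' paired); `paired = TRUE` matches observations by position, which is
#' meant for within-patient comparisons such as NEP-D vs NEP-T.
#'
#' @param data Data frame.
#' @param value Name of the numeric column to compare.
#' @param group Name of a two-level grouping column, or `NULL` when `value2`
#'   names a second column compared pairwise against `value`.
#' @param value2 Optional second value column for the paired/two-column form.
#' @param paired Logical.
#' @param var_equal Logical; classic Student test instead of Welch when `TRUE`.
#' @return One-row tibble: group labels, `mean_a`, `sem_a`, `n_a`, `mean_b`,
#'   `sem_b`, `n_b`, `t_stat`, `df`, `p_value` (`NA`s when a group has fewer
#'   than 2 observations).
#' @export
#' @examples
#' cohort <- nep_score(simulate_cohort(sim_config(n = 30), seed = 11))
#' compare_group_means(cohort, "nep_t", group = "vital_status")
#' compare_group_means(cohort, "nep_d", value2 = "nep_t", paired = TRUE)
compare_group_means <- function(data, value, group = NULL, value2 = NULL,
                                paired = FALSE, var_equal = FALSE) {
  if (!is.null(value2)) {
    a <- data[[value]]
    b <- data[[value2]]
    label_a <- value
    label_b <- value2
  } else {
    if (is.null(group)) abort_validation("supply either group or value2")
    g <- data[[group]]
    levels_g <- sort(unique(as.character(g)))
    if (length(levels_g) != 2) {
      abort_validation("group column must have exactly 2 levels, found %d",
                       length(levels_g))
    }
    a <- data[[value]][as.character(g) == levels_g[1]]
    b <- data[[value]][as.character(g) == levels_g[2]]
    label_a <- levels_g[1]
    label_b <- levels_g[2]
  }
  if (paired && length(a) != length(b)) {
    abort_validation("paired comparison requires equal-length groups")
  }
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  out <- tibble::tibble(
    group_a = label_a, group_b = label_b,
    n_a = length(a), mean_a = mean(a), sem_a = sem(a),
    n_b = length(b), mean_b = mean(b), sem_b = sem(b),
    paired = paired,
    t_stat = NA_real_, df = NA_real_, p_value = NA_real_
  )
  if (length(a) >= 2 && length(b) >= 2) {
    tt <- tryCatch(
      stats::t.test(a, b, paired = paired, var.equal = var_equal),
      error = function(e) NULL
    )
    if (!is.null(tt) && !is.nan(unname(tt$statistic))) {
      out$t_stat <- unname(tt$statistic)
      out$df <- unname(tt$parameter)
      out$p_value <- tt$p.value
    } else if (isTRUE(all.equal(mean(a), mean(b)))) {
      # zero-variance degenerate case with equal means: nothing to reject
      out$t_stat <- 0
      out$p_value <- 1
    }
  }
  out
}

#' Reconstruct a 2x2 table from its published margins
#'
#' Publications often print only a cohort size, a death count, and the
#' percentage dead above and below a cutoff. This enumerates every
#' nonnegative-integer 2x2 table with those margins, computes each table's
#' group death percentages at one-decimal rounding, and ranks tables by
#' their absolute discrepancy from the printed percentages. When the printed
#' values are internally consistent exactly one table has discrepancy zero;
#' otherwise the minimum-discrepancy table is the published table up to
#' rounding noise. Uniqueness of the minimiser should be checked via the
#' returned table before trusting the reconstruction.
#'
#' @param n Cohort size.
#' @param n_dead Total deaths.
#' @param pct_dead_high Printed percent dead in the `score >= threshold` group.
#' @param pct_dead_low Printed percent dead in the `score < threshold` group.
#' @return A tibble of all feasible tables (`tp`, `fp`, `fn`, `tn`, group
#'   sizes, percentages and `discrepancy`, the sum of absolute differences
#'   from the printed percentages), sorted by discrepancy; the first row is
#'   the reconstruction. Tables with an empty group are excluded since the
#'   printed percentages imply both groups are populated.
#' @export
#' @examples
#' # the published table behind "80% of high-score and 23.5% of low-score
#' # patients were dead" in a 27-patient cohort with 12 deaths:
#' reconstruct_confusion(27, 12, 80, 23.5)[1, ]
reconstruct_confusion <- function(n, n_dead, pct_dead_high, pct_dead_low) {
  stopifnot(n >= 2, n_dead >= 0, n_dead <= n)
  grid <- tidyr::expand_grid(tp = 0:n_dead, fp = 0:(n - n_dead))
  grid$fn <- n_dead - grid$tp
  grid$tn <- (n - n_dead) - grid$fp
  grid$n_high <- grid$tp + grid$fp
  grid$n_low <- grid$fn + grid$tn
  grid <- dplyr::filter(grid, .data$n_high > 0, .data$n_low > 0)
  grid$pct_high <- as_percent(grid$tp / grid$n_high)
  grid$pct_low <- as_percent(grid$fn / grid$n_low)
  grid$discrepancy <- abs(grid$pct_high - pct_dead_high) +
    abs(grid$pct_low - pct_dead_low)
  dplyr::arrange(tibble::as_tibble(grid), .data$discrepancy, .data$tp)
}
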