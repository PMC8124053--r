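#' Kaplan-Meier survival curve for a cohort
#'
#' Product-limit estimate of overall survival from diagnosis, with patients
#' alive at the end of follow-up treated as right-censored at their
#' follow-up time. Ties at the same time are resolved events-first, the
#' product-limit convention: censored patients at time t remain in the risk
#' set for the events at t.
#'
#' @param data Cohort data frame.
#' @param time Name of the follow-up time column (months, positive).
#' @param status Name of the vital-status column (`"alive"`/`"dead"` or
#'   logical dead indicator).
#' @return An object of class `nep_km` wrapping a [survival::survfit()]
#'   fit; `tidy()` returns the step function as a tibble (`time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`, `std_error`), `glance()` the number
#'   at risk, events and KM median, and `autoplot()` draws the step curve.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n = 20), seed = 5)
#' km <- km_fit(cohort)
#' tidy(km)
km_fit <- function(data, time = "os_months", status = "vital_status") {
  times <- data[[time]]
  dead <- is_dead(data[[status]])
  if (length(times) == 0 || length(times) != length(dead)) {
    abort_validation("time and status columns must be nonempty and aligned")
  }
  if (anyNA(times) || any(times <= 0)) {
    abort_validation("survival times must be positive and non-missing")
  }
  fit <- survival::survfit(survival::Surv(times, dead) ~ 1,
                           conf.type = "none")
  structure(
    list(fit = fit, n = length(times), n_dead = sum(dead),
         time = times, dead = dead),
    class = "nep_km"
  )
}

#' @export
tidy.nep_km <- function(x, ...) {
  s <- summary(x$fit, censored = TRUE)
  tibble::tibble(
    time = s$time,
    n_risk = s$n.risk,
    n_event = s$n.event,
    n_censor = s$n.censor,
    survival = s$surv,
    std_error = s$std.err
  )
}

#' @export
glance.nep_km <- function(x, ...) {
  med <- unname(summary(x$fit)$table["median"])
  tibble::tibble(n = x$n, n_dead = x$n_dead,
                 median_survival = as.numeric(med))
}

#' @export
print.nep_km <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d patients, %d deaths\n", x$n, x$n_dead))
  print(glance(x))
  invisible(x)
}

#' @export
autoplot.nep_km <- function(object, ...) {
  d <- tidy(object)
  d0 <- dplyr::bind_rows(
    tibble::tibble(time = 0, survival = 1),
    d[, c("time", "survival")]
  )
  ggplot2::ggplot(d0, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(
      data = dplyr::filter(d, .data$n_censor > 0),
      shape = 3
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months from diagnosis", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' Survival function evaluated at given times
#'
#' @param km A `nep_km` object.
#' @param times Times (months) at which to evaluate S(t).
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(km, times) {
  s <- summary(km$fit, times = times, extend = TRUE)
  s$surv
}

#' Stratified survival analysis at a score threshold
#'
#' Splits a scored cohort at `score >= threshold` and compares survival
#' between the strata: Kaplan-Meier curves, a log-rank test, and for each
#' stratum the arithmetic mean of observed follow-up time with its SEM
#' (reported here as "mean OS" for comparability with clinical practice —
#' note that for censored patients this conflates follow-up duration with
#' survival, so the KM median is reported alongside), the death proportion,
#' and a Welch t test on the mean times.
#'
#' @inheritParams km_fit
#' @param score Name of the score column.
#' @param threshold Numeric cutoff defining the high stratum.
#' @return An object of class `nep_strata`: `strata` (per-stratum tibble
#'   with n, deaths, mean/SEM OS, KM median), `logrank_chi2`, `logrank_p`,
#'   `mean_test` (t-test tibble from [compare_group_means()]), and the two
#'   `nep_km` fits. With an empty stratum the nonempty stratum is summarized
#'   and all tests are `NA`.
#' @export
#' @examples
#' cohort <- nep_score(simulate_cohort(sim_config(n = 40), seed = 2))
#' stratify_survival(cohort, threshold = 116, score = "nep_d")
stratify_survival <- function(data, threshold, score = "nep_d",
                              time = "os_months", status = "vital_status") {
  scores <- data[[score]]
  times <- data[[time]]
  dead <- is_dead(data[[status]])
  high <- scores >= threshold
  labels <- c(sprintf("%s < %s", score, format(threshold)),
              sprintf("%s >= %s", score, format(threshold)))
  sem <- function(x) if (length(x) >= 2) stats::sd(x) / sqrt(length(x)) else 0

  stratum_row <- function(idx, label) {
    if (sum(idx) == 0) {
      return(tibble::tibble(stratum = label, n = 0L, n_dead = 0L,
                            p_dead = NA_real_, mean_os = NA_real_,
                            sem_os = NA_real_, km_median = NA_real_))
    }
    km <- km_fit(data.frame(t = times[idx], s = dead[idx]),
                 time = "t", status = "s")
    tibble::tibble(
      stratum = label, n = sum(idx), n_dead = sum(dead[idx]),
      p_dead = mean(dead[idx]),
      mean_os = mean(times[idx]), sem_os = sem(times[idx]),
      km_median = glance(km)$median_survival
    )
  }
  strata <- dplyr::bind_rows(stratum_row(!high, labels[1]),
                             stratum_row(high, labels[2]))

  logrank_chi2 <- NA_real_
  logrank_p <- NA_real_
  mean_test <- NULL
  if (all(strata$n > 0)) {
    sd_fit <- survival::survdiff(survival::Surv(times, dead) ~ high)
    logrank_chi2 <- unname(sd_fit$chisq)
    logrank_p <- stats::pchisq(sd_fit$chisq, df = 1, lower.tail = FALSE)
    mean_test <- compare_group_means(
      data.frame(os = times, grp = ifelse(high, "high", "low")),
      value = "os", group = "grp"
    )
  }
  fits <- list(
    low = if (any(!high)) km_fit(data.frame(t = times[!high], s = dead[!high]),
                                 "t", "s") else NULL,
    high = if (any(high)) km_fit(data.frame(t = times[high], s = dead[high]),
                                 "t", "s") else NULL
  )
  structure(
    list(strata = strata, logrank_chi2 = logrank_chi2, logrank_p = logrank_p,
         mean_test = mean_test, fits = fits, score = score,
         threshold = threshold),
    class = "nep_strata"
  )
}

#' @export
tidy.nep_strata <- function(x, ...) {
  labels <- x$strata$stratum
  curves <- purrr::imap_dfr(
    list(x$fits$low, x$fits$high),
    function(fit, i) {
      if (is.null(fit)) return(NULL)
      d <- tidy(fit)
      d$stratum <- labels[as.integer(i)]
      d
    }
  )
  dplyr::relocate(curves, "stratum")
}

#' @export
glance.nep_strata <- function(x, ...) {
  tibble::tibble(
    score = x$score, threshold = x$threshold,
    n_low = x$strata$n[1], n_high = x$strata$n[2],
    mean_os_low = x$strata$mean_os[1], mean_os_high = x$strata$mean_os[2],
    logrank_chi2 = x$logrank_chi2, logrank_p = x$logrank_p,
    mean_t_p = if (is.null(x$mean_test)) NA_real_ else x$mean_test$p_value
  )
}

#' @export
print.nep_strata <- function(x, ...) {
  cat(sprintf("Survival stratified at %s >= %s\n", x$score,
              format(x$threshold)))
  print(x$strata)
  if (!is.na(x$logrank_chi2)) {
    cat(sprintf("Log-rank chi2 = %.3f, p = %.4f\n", x$logrank_chi2,
                x$logrank_p))
  } else {
    cat("Log-rank test not computable (empty stratum).\n")
  }
  invisible(x)
}

#' @export
autoplot.nep_strata <- function(object, ...) {
  d <- tidy(object)
  d0 <- dplyr::bind_rows(
    tibble::tibble(stratum = unique(d$stratum), time = 0, survival = 1),
    d[, c("stratum", "time", "survival")]
  )
  ggplot2::ggplot(d0, ggplot2::aes(x = .data$time, y = .data$survival,
                                   linetype = .data$stratum)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months from diagnosis", y = "Survival probability",
                  linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Five-year survival status by score stratum
#'
#' A patient is alive at five years if follow-up reaches 60 months
#' (alive at exactly 60 counts as alive; a death at or after 60 months also
#' counts, the patient having survived the first five years), not alive if
#' death occurred before 60 months, and not evaluable when follow-up was
#' censored before 60 months.
#'
#' @inheritParams stratify_survival
#' @return A tibble with one row per stratum: `n`, `alive_5y`,
#'   `dead_before_5y`, `not_evaluable`, `evaluable`, `p_alive_5y` (among
#'   evaluable patients).
#' @export
five_year_survival <- function(data, threshold, score = "nep_d",
                               time = "os_months", status = "vital_status") {
  scores <- data[[score]]
  times <- data[[time]]
  dead <- is_dead(data[[status]])
  high <- scores >= threshold
  status_5y <- dplyr::case_when(
    times >= 60 ~ "alive_5y",
    dead ~ "dead_before_5y",
    TRUE ~ "not_evaluable"
  )
  labels <- c(sprintf("%s < %s", score, format(threshold)),
              sprintf("%s >= %s", score, format(threshold)))
  tab <- tibble::tibble(
    stratum = factor(ifelse(high, labels[2], labels[1]), levels = labels),
    status_5y = factor(status_5y,
                       levels = c("alive_5y", "dead_before_5y",
                                  "not_evaluable"))
  )
  out <- tab |>
    dplyr::count(.data$stratum, .data$status_5y, .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "status_5y", values_from = "n")
  out$n <- out$alive_5y + out$dead_before_5y + out$not_evaluable
  out$evaluable <- out$alive_5y + out$dead_before_5y
  out$p_alive_5y <- safe_ratio(out$alive_5y, out$evaluable)
  dplyr::relocate(out, "stratum", "n")
}

#' Overall mortality of a cohort
#'
#' @param data Cohort data frame.
#' @param status Name of the vital-status column.
#' @return One-row tibble: `n_dead`, `n_total`, `mortality_pct` (percent,
#'   one decimal, rounded half up).
#' @export
#' @examples
#' overall_mortality(data.frame(vital_status = rep(c("dead", "alive"), c(12, 15))))
overall_mortality <- function(data, status = "vital_status") {
  dead <- is_dead(data[[status]])
  if (length(dead) == 0) abort_validation("cohort must be nonempty")
  tibble::tibble(
    n_dead = sum(dead), n_total = length(dead),
    mortality_pct = as_percent(mean(dead), 1)
  )
}
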