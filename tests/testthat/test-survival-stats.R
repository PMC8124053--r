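km_of <- function(times, dead) {
  km_fit(data.frame(os_months = times, vital_status = dead))
}

test_that("product-limit estimates match hand-computed step functions", {
  s1 <- tidy(km_of(c(10, 20), c(TRUE, TRUE)))
  expect_equal(s1$survival, c(0.5, 0))
  # all censored: curve never drops
  s2 <- tidy(km_of(c(10, 20), c(FALSE, FALSE)))
  expect_true(all(s2$survival == 1))
  # 3/4 * (drop at 18 with 2 at risk) * (drop at 24 with 1 at risk)
  s3 <- tidy(km_of(c(6, 12, 18, 24), c(TRUE, FALSE, TRUE, TRUE)))
  expect_equal(s3$survival[s3$time == 6], 0.75)
  expect_equal(s3$survival[s3$time == 18], 0.375)
  expect_equal(s3$survival[s3$time == 24], 0)
  expect_error(km_of(numeric(), logical()),
               class = "nepscore_validation_error")
  expect_error(km_of(c(0, 5), c(TRUE, TRUE)),
               class = "nepscore_validation_error")
})

test_that("estimator equals brute-force product limit on all small cohorts", {
  for (n in 1:6) {
    times <- seq_len(n) * 3
    for (mask in 0:(2^n - 1)) {
      dead <- as.logical(bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1))
      got <- tidy(km_of(times, dead))
      want <- brute_km(times, dead)
      expect_equal(km_survival_at(km_of(times, dead), want$time),
                   want$survival, tolerance = 1e-12)
      # survfit drops nothing: every observed time appears once
      expect_equal(got$time, want$time)
      expect_equal(got$survival, want$survival, tolerance = 1e-12)
    }
  }
})

test_that("ties are resolved events-first", {
  # death and censoring at t=10: the censored patient is still at risk for
  # the death, so S(10) = 1 - 1/3 with a third patient at 20
  times <- c(10, 10, 20)
  dead <- c(TRUE, FALSE, FALSE)
  got <- tidy(km_of(times, dead))
  expect_equal(got$survival[got$time == 10], 2 / 3)
  expect_equal(got, dplyr::arrange(got, time))
  want <- brute_km(times, dead)
  expect_equal(km_survival_at(km_of(times, dead), want$time), want$survival)
})

test_that("without censoring the curve is the empirical survival fraction", {
  set.seed(31)
  times <- sample(1:100, 25, replace = TRUE)
  km <- km_of(times, rep(TRUE, 25))
  at <- sort(unique(times))
  expect_equal(km_survival_at(km, at),
               vapply(at, function(t) mean(times > t), 0))
})

test_that("survival curve invariants hold on simulated cohorts", {
  cohort <- simulate_cohort(sim_config(n = 60), seed = 12)
  d <- tidy(km_fit(cohort))
  expect_true(all(d$survival >= 0 & d$survival <= 1))
  expect_true(all(diff(d$survival) <= 1e-12))
  expect_true(all(diff(d$n_risk) < 0))
  expect_equal(d$n_risk[1], 60)
})

test_that("stratified survival reports per-stratum summaries and a log-rank test", {
  cohort <- nep_score(simulate_cohort(sim_config(n = 50), seed = 4))
  st <- stratify_survival(cohort, 116, score = "nep_d")
  expect_equal(sum(st$strata$n), 50)
  expect_equal(sum(st$strata$n_dead),
               sum(cohort$vital_status == "dead"))
  # mean of all equals the weighted mean of stratum means
  expect_equal(
    sum(st$strata$mean_os * st$strata$n) / 50,
    mean(cohort$os_months)
  )
  expect_false(is.na(st$logrank_chi2))
  g <- glance(st)
  expect_equal(g$n_low + g$n_high, 50)
  curves <- tidy(st)
  expect_setequal(unique(curves$stratum), st$strata$stratum)
})

test_that("log-rank is zero for identical strata and invariant to relabeling", {
  times <- c(5, 12, 20, 33, 47)
  dead <- c(TRUE, FALSE, TRUE, TRUE, FALSE)
  twin <- tibble::tibble(
    nep_d = rep(c(10, 200), each = 5),
    os_months = rep(times, 2),
    vital_status = rep(dead, 2)
  )
  st <- stratify_survival(twin, 116)
  expect_equal(st$logrank_chi2, 0, tolerance = 1e-10)
  expect_equal(st$logrank_p, 1, tolerance = 1e-6)
  # relabeling: flip which stratum is "high"
  flipped <- twin
  flipped$nep_d <- rep(c(200, 10), each = 5)
  expect_equal(stratify_survival(flipped, 116)$logrank_chi2,
               st$logrank_chi2, tolerance = 1e-10)
})

test_that("single-stratum edge cases are summarized without tests", {
  const <- tibble::tibble(nep_d = c(150, 160, 170),
                          os_months = c(40, 40, 40),
                          vital_status = "dead")
  st <- stratify_survival(const, 116)
  high <- st$strata[2, ]
  expect_equal(high$mean_os, 40)
  expect_equal(high$sem_os, 0)
  expect_equal(st$strata$n[1], 0)
  expect_true(is.na(st$logrank_chi2))
})

test_that("a harsher hazard in the high stratum lowers its mean survival in most replicates", {
  set.seed(99)
  # default slope b = 0.01 per point; n = 100 per replicate so the mean-OS
  # estimator noise does not mask the generator's monotone hazard
  cfg <- sim_config(n = 100)
  lower <- 0
  valid <- 0
  for (r in 1:500) {
    cohort <- nep_score(simulate_cohort(cfg))
    high <- cohort$nep_t >= 145
    if (!any(high) || all(high)) next
    valid <- valid + 1
    if (mean(cohort$os_months[high]) < mean(cohort$os_months[!high])) {
      lower <- lower + 1
    }
  }
  expect_gt(valid, 450)
  expect_gte(lower / valid, 0.95)
})

test_that("five-year survival classifies deaths, survivors and censored correctly", {
  cohort <- tibble::tibble(
    nep_d = c(50, 50, 50, 150, 150, 150),
    os_months = c(30, 70, 40, 61, 60, 59),
    vital_status = c("dead", "alive", "alive", "dead", "alive", "alive")
  )
  out <- five_year_survival(cohort, 90)
  low <- out[out$stratum == "nep_d < 90", ]
  high <- out[out$stratum == "nep_d >= 90", ]
  expect_equal(low$alive_5y, 1)          # alive with 70 months
  expect_equal(low$dead_before_5y, 1)    # dead at 30
  expect_equal(low$not_evaluable, 1)     # censored at 40
  expect_equal(high$alive_5y, 2)         # dead at 61 and alive at exactly 60
  expect_equal(high$dead_before_5y, 0)
  expect_equal(high$not_evaluable, 1)    # censored at 59
  expect_equal(sum(out$n), 6)
})

test_that("overall mortality matches the published 12-of-27 formatting", {
  study <- data.frame(vital_status = rep(c("dead", "alive"), c(12, 15)))
  out <- overall_mortality(study)
  expect_equal(out$mortality_pct, 44.4)
  expect_equal(overall_mortality(
    data.frame(vital_status = rep("alive", 8)))$mortality_pct, 0)
  expect_equal(overall_mortality(
    data.frame(vital_status = rep("dead", 27)))$mortality_pct, 100)
  expect_error(overall_mortality(data.frame(vital_status = character())),
               class = "nepscore_validation_error")
})
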