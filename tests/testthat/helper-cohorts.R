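# Independent product-limit oracle: walks the risk set event time by event
# time, events before censorings at ties. Returns survival evaluated after
# each distinct observed time.
brute_km <- function(times, dead) {
  ord <- order(times, !dead)  # at ties, deaths first
  times <- times[ord]
  dead <- dead[ord]
  uts <- sort(unique(times))
  surv <- numeric(length(uts))
  s <- 1
  for (i in seq_along(uts)) {
    t <- uts[i]
    at_risk <- sum(times >= t)
    d <- sum(times == t & dead)
    if (at_risk > 0 && d > 0) s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  data.frame(time = uts, survival = surv)
}

# Independent point-table oracle written as explicit per-band branches,
# deliberately not sharing code with the package's lookup.
oracle_points <- function(age, site, surgery, functional, ki67, timing) {
  a <- if (age < 46) 0 else if (age <= 65) 28 else 58
  s <- if (site == "pancreas") 59 else 0
  su <- if (surgery) 0 else 100
  f <- if (functional) 32 else 0
  k <- if (ki67 < 3) 0 else if (ki67 <= 20) 12 else 57
  tm <- switch(timing, synchronous = 0, metachronous_gt24 = 38,
               metachronous_le24 = 72)
  c(nep_d = a + s + su + f + k, nep_t = a + s + su + f + k + tm)
}

# A deterministic 27-patient cohort whose per-variable counts reproduce the
# published general-features table (17 male, 14 pancreatic, 21 resected,
# 9 functional, Ki67 17/7/3, 12 synchronous, 12 dead). The joint structure
# is arbitrary (columns are built independently).
table2_cohort <- function() {
  rep_levels <- function(levels, counts) rep(levels, counts)
  tibble::tibble(
    patient_id = sprintf("T%02d", 1:27),
    age_at_diagnosis = seq(26, 84, length.out = 27),
    sex = rep_levels(c("male", "female"), c(17, 10)),
    primary_site = rep_levels(c("ileum", "pancreas"), c(13, 14)),
    primary_surgery = rep_levels(c(TRUE, FALSE), c(21, 6)),
    functional = rep_levels(c(TRUE, FALSE), c(9, 18)),
    ki67_pct = rep_levels(c(1, 10, 30), c(17, 7, 3)),
    metastasis_timing = rep_levels(
      c("synchronous", "metachronous_gt24", "metachronous_le24"),
      c(12, 8, 7)
    ),
    well_differentiated = TRUE,
    stage_iv = TRUE,
    vital_status = rep_levels(c("dead", "alive"), c(12, 15)),
    os_months = seq(25, 130, length.out = 27)
  )
}

# Random scored outcome data for property tests.
random_score_outcome <- function(n) {
  list(
    scores = sample(0:378, n, replace = TRUE),
    dead = sample(c(TRUE, FALSE), n, replace = TRUE)
  )
}
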