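#' Component point scores
#'
#' Each function maps one clinical characteristic to its NEP point
#' contribution under a score table (default: the published weights,
#' [nep_score_table()]). All are vectorized and validate their input:
#' out-of-domain values raise a validation error rather than returning `NA`.
#'
#' @param age_at_diagnosis Age in years at diagnosis (positive).
#' @param primary_site `"ileum"` or `"pancreas"`, or a site listed in the
#'   table's `site_aliases`.
#' @param primary_surgery Logical: was the primary tumor resected?
#' @param functional Logical: hormone-related symptoms present?
#' @param ki67_pct Ki67 (Mib-1) proliferation index, percent in `[0, 100]`.
#' @param metastasis_timing One of `"synchronous"`, `"metachronous_gt24"`,
#'   `"metachronous_le24"` (metachronous more/less than 24 months after
#'   diagnosis).
#' @param table A score table, see [nep_score_table()].
#' @return Integer vector of points.
#' @name score-components
#' @examples
#' score_age(c(44, 50, 66))
#' score_site("pancreas")
#' score_ki67(c(2, 15, 25))
NULL

#' @rdname score-components
#' @export
score_age <- function(age_at_diagnosis, table = nep_score_table()) {
  if (!is.numeric(age_at_diagnosis) || any(is.na(age_at_diagnosis)) ||
      any(age_at_diagnosis <= 0)) {
    abort_validation("age_at_diagnosis must be a positive number of years")
  }
  pts <- table$age
  unname(ifelse(age_at_diagnosis < 46, pts[["under_46"]],
                ifelse(age_at_diagnosis <= 65, pts[["from_46_to_65"]],
                       pts[["over_65"]])))
}

#' @rdname score-components
#' @export
score_site <- function(primary_site, table = nep_score_table()) {
  site <- tolower(trimws(as.character(primary_site)))
  aliases <- table$site_aliases
  mapped <- ifelse(site %in% names(aliases), unname(aliases[site]), site)
  unknown <- !mapped %in% names(table$site)
  if (any(unknown, na.rm = TRUE) || anyNA(mapped)) {
    abort_validation(
      "unknown primary site %s: not one of %s and no alias configured",
      paste(unique(sQuote(site[unknown | is.na(mapped)])), collapse = ", "),
      paste(names(table$site), collapse = "/")
    )
  }
  unname(table$site[mapped])
}

#' @rdname score-components
#' @export
score_surgery <- function(primary_surgery, table = nep_score_table()) {
  x <- parse_clinical_logical(primary_surgery, "primary_surgery")
  if (anyNA(x)) abort_validation("primary_surgery is required (yes/no)")
  unname(ifelse(x, table$surgery[["yes"]], table$surgery[["no"]]))
}

#' @rdname score-components
#' @export
score_functional <- function(functional, table = nep_score_table()) {
  x <- parse_clinical_logical(functional, "functional")
  if (anyNA(x)) abort_validation("functional status is required (yes/no)")
  unname(ifelse(x, table$functional[["yes"]], table$functional[["no"]]))
}

#' @rdname score-components
#' @export
score_ki67 <- function(ki67_pct, table = nep_score_table()) {
  if (!is.numeric(ki67_pct) || any(is.na(ki67_pct)) ||
      any(ki67_pct < 0 | ki67_pct > 100)) {
    abort_validation("ki67_pct must be a percentage in [0, 100]")
  }
  pts <- table$ki67
  unname(ifelse(ki67_pct < 3, pts[["under_3"]],
                ifelse(ki67_pct <= 20, pts[["from_3_to_20"]],
                       pts[["over_20"]])))
}

#' @rdname score-components
#' @export
score_timing <- function(metastasis_timing, table = nep_score_table()) {
  timing <- tolower(trimws(as.character(metastasis_timing)))
  bad <- !timing %in% names(table$timing)
  if (any(bad)) {
    abort_validation(
      "metastasis_timing must be one of %s, got %s",
      paste(names(table$timing), collapse = "/"),
      paste(unique(sQuote(timing[bad])), collapse = ", ")
    )
  }
  unname(table$timing[timing])
}

#' Convert months-to-first-metastasis to a timing category
#'
#' 0 months means metastases were present at diagnosis (synchronous); later
#' appearances are split at the 24-month boundary used by the point table.
#'
#' @param months Months from diagnosis to first metastasis (0 = synchronous).
#' @return Character vector of timing categories.
#' @export
#' @examples
#' timing_from_months(c(0, 12, 36))
timing_from_months <- function(months) {
  if (!is.numeric(months) || any(is.na(months)) || any(months < 0)) {
    abort_validation("months_to_metastasis must be nonnegative months")
  }
  ifelse(months == 0, "synchronous",
         ifelse(months <= 24, "metachronous_le24", "metachronous_gt24"))
}

#' Compute NEP-D, NEP-T and Delta-NEP for a cohort
#'
#' Appends the six component point columns and the three scores to a cohort
#' table. NEP-D (diagnosis-time score) is the sum of the five components
#' known at diagnosis: age, primary site, primary surgery, functional status
#' and Ki67 band. NEP-T (end-of-follow-up score) additionally adds the
#' metastasis-timing points, so `delta_nep = nep_t - nep_d` equals the
#' timing component exactly and is 0 for patients with synchronous
#' metastases. Risk classes for both scores are attached per
#' [nep_risk_class()].
#'
#' @param data A cohort data frame with columns `age_at_diagnosis`,
#'   `primary_site`, `primary_surgery`, `functional`, `ki67_pct`, and
#'   `metastasis_timing` (see [read_cohort()] for the full schema).
#' @param table A score table, see [nep_score_table()].
#' @return The input as a tibble with columns `age_points`, `site_points`,
#'   `surgery_points`, `functional_points`, `ki67_points`, `timing_points`,
#'   `nep_d`, `nep_t`, `delta_nep`, `risk_class_d`, `risk_class_t` appended.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n = 5), seed = 1)
#' nep_score(cohort)[, c("nep_d", "nep_t", "delta_nep")]
nep_score <- function(data, table = nep_score_table()) {
  validate_score_table(table)
  needed <- c("age_at_diagnosis", "primary_site", "primary_surgery",
              "functional", "ki67_pct", "metastasis_timing")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort_validation("missing required columns: %s",
                     paste(missing_cols, collapse = ", "))
  }
  out <- tibble::as_tibble(data)
  out$age_points <- score_age(out$age_at_diagnosis, table)
  out$site_points <- score_site(out$primary_site, table)
  out$surgery_points <- score_surgery(out$primary_surgery, table)
  out$functional_points <- score_functional(out$functional, table)
  out$ki67_points <- score_ki67(out$ki67_pct, table)
  out$timing_points <- score_timing(out$metastasis_timing, table)
  out$nep_d <- out$age_points + out$site_points + out$surgery_points +
    out$functional_points + out$ki67_points
  out$nep_t <- out$nep_d + out$timing_points
  out$delta_nep <- out$nep_t - out$nep_d
  out$risk_class_d <- nep_risk_class(out$nep_d)
  out$risk_class_t <- nep_risk_class(out$nep_t)
  out
}

#' Risk class for a NEP score
#'
#' The published 10-year survival bands: low risk for scores up to 70
#' (> 70% survival), intermediate for 71-198 (30-70% survival), high for
#' 199 and above (< 30% survival). The three classes partition the
#' nonnegative integers with no gaps.
#'
#' @param score Integer NEP score(s), nonnegative.
#' @return An ordered factor with levels `low < intermediate < high`.
#' @export
#' @examples
#' nep_risk_class(c(70, 71, 198, 199))
nep_risk_class <- function(score) {
  if (!is.numeric(score) || any(is.na(score)) || any(score < 0)) {
    abort_validation("score must be a nonnegative number")
  }
  cls <- ifelse(score <= 70, "low",
                ifelse(score <= 198, "intermediate", "high"))
  factor(cls, levels = c("low", "intermediate", "high"), ordered = TRUE)
}

#' Eligibility screen for the score's target population
#'
#' The score applies to stage IV well-differentiated entero-pancreatic
#' neuroendocrine neoplasms with more than 24 months of follow-up; poorly
#' differentiated carcinomas (NEC G3) and other primary sites are excluded.
#'
#' @param data Cohort data frame with columns `stage_iv`,
#'   `well_differentiated`, `primary_site`, `os_months`.
#' @param table Score table (its `site_aliases` extend the admissible sites).
#' @return The input as a tibble with `eligible` (logical) and
#'   `ineligibility_reasons` (character, `NA` when eligible, otherwise a
#'   `"; "`-joined list of failed criteria) appended.
#' @export
check_eligibility <- function(data, table = nep_score_table()) {
  needed <- c("stage_iv", "well_differentiated", "primary_site", "os_months")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort_validation("missing required columns: %s",
                     paste(missing_cols, collapse = ", "))
  }
  out <- tibble::as_tibble(data)
  stage_iv <- parse_clinical_logical(out$stage_iv, "stage_iv")
  wd <- parse_clinical_logical(out$well_differentiated, "well_differentiated")
  site <- tolower(trimws(as.character(out$primary_site)))
  admissible <- c(names(table$site), names(table$site_aliases))
  os <- out$os_months

  reasons <- purrr::pmap_chr(
    list(stage_iv, wd, site, os),
    function(s4, w, st, o) {
      r <- character()
      if (!isTRUE(s4)) r <- c(r, "not stage IV")
      if (!isTRUE(w)) r <- c(r, "not well differentiated")
      if (!st %in% admissible) r <- c(r, sprintf("primary site '%s' not entero-pancreatic", st))
      if (is.na(o) || o <= 24) r <- c(r, "follow-up <= 24 months")
      if (length(r) == 0) NA_character_ else paste(r, collapse = "; ")
    }
  )
  out$eligible <- is.na(reasons)
  out$ineligibility_reasons <- reasons
  out
}
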