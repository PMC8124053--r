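cohort_columns <- function() {
  c("patient_id", "age_at_diagnosis", "sex", "primary_site",
    "primary_surgery", "functional", "ki67_pct", "metastasis_timing",
    "well_differentiated", "stage_iv", "vital_status", "os_months")
}

#' Read and validate a cohort CSV
#'
#' Expects snake_case headers: `patient_id`, `age_at_diagnosis`, `sex`,
#' `primary_site`, `primary_surgery`, `functional`, `ki67_pct`,
#' `metastasis_timing` (or `months_to_metastasis`), `well_differentiated`,
#' `stage_iv`, `vital_status`, `os_months`. Booleans are accepted as
#' yes/no, true/false or 1/0 (case-insensitive). Metastasis timing may be
#' given either as a category or as months from diagnosis to first
#' metastasis (0 = synchronous); when both columns are present the numeric
#' one wins, with a warning. Rows failing validation are collected with
#' their row number and reason — never silently dropped; in strict mode any
#' issue aborts.
#'
#' @param path CSV file path.
#' @param table Score table whose `site_aliases` extend the admissible
#'   primary sites.
#' @param strict Abort on the first validation issue instead of filtering.
#' @return A cohort tibble of the valid rows, with the issue table (row,
#'   patient_id, reason) attached as attribute `"issues"`; see
#'   [cohort_issues()].
#' @export
read_cohort <- function(path, table = nep_score_table(), strict = FALSE) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  validate_cohort(raw, table = table, strict = strict)
}

#' Validate an in-memory cohort table
#'
#' The validation backend of [read_cohort()], usable on any data frame.
#'
#' @inheritParams read_cohort
#' @param data Data frame with the cohort columns.
#' @export
validate_cohort <- function(data, table = nep_score_table(), strict = FALSE) {
  raw <- tibble::as_tibble(data)
  has_months <- "months_to_metastasis" %in% names(raw)
  has_timing <- "metastasis_timing" %in% names(raw)
  required <- setdiff(cohort_columns(), "metastasis_timing")
  missing_cols <- setdiff(required, names(raw))
  if (!has_months && !has_timing) {
    missing_cols <- c(missing_cols, "metastasis_timing (or months_to_metastasis)")
  }
  if (length(missing_cols) > 0) {
    abort_validation("cohort is missing required column(s): %s",
                     paste(missing_cols, collapse = ", "))
  }
  if (has_months && has_timing) {
    rlang::warn(paste("both metastasis_timing and months_to_metastasis",
                      "present; the numeric months column takes precedence"))
  }

  admissible_sites <- c(names(table$site), names(table$site_aliases))
  timing_levels <- names(table$timing)

  parse_row <- function(i) {
    row <- raw[i, ]
    issues <- character()
    num <- function(x) suppressWarnings(as.numeric(x))
    lgl <- function(x, field) {
      tryCatch(parse_clinical_logical(x, field),
               nepscore_validation_error = function(e) NA)
    }

    age <- num(row$age_at_diagnosis)
    if (is.na(age) || age <= 0) issues <- c(issues, "age_at_diagnosis must be a positive number")

    sex <- tolower(trimws(as.character(row$sex)))
    if (sex %in% c("m", "f")) sex <- c(m = "male", f = "female")[[sex]]
    if (!sex %in% c("male", "female")) issues <- c(issues, sprintf("sex '%s' not male/female", row$sex))

    site <- tolower(trimws(as.character(row$primary_site)))
    if (!site %in% admissible_sites) {
      issues <- c(issues, sprintf("primary_site '%s' not recognized and no alias configured", site))
    }

    surgery <- lgl(row$primary_surgery, "primary_surgery")
    if (is.na(surgery)) issues <- c(issues, "primary_surgery must be yes/no")
    func <- lgl(row$functional, "functional")
    if (is.na(func)) issues <- c(issues, "functional must be yes/no")
    wd <- lgl(row$well_differentiated, "well_differentiated")
    if (is.na(wd)) issues <- c(issues, "well_differentiated must be yes/no")
    s4 <- lgl(row$stage_iv, "stage_iv")
    if (is.na(s4)) issues <- c(issues, "stage_iv must be yes/no")

    ki67 <- num(row$ki67_pct)
    if (is.na(ki67) || ki67 < 0 || ki67 > 100) {
      issues <- c(issues, sprintf("ki67_pct '%s' outside [0, 100]", row$ki67_pct))
    }

    timing <- NA_character_
    if (has_months && !is.na(row$months_to_metastasis) &&
        trimws(row$months_to_metastasis) != "") {
      mm <- num(row$months_to_metastasis)
      if (is.na(mm) || mm < 0) {
        issues <- c(issues, "months_to_metastasis must be nonnegative")
      } else {
        timing <- timing_from_months(mm)
      }
    } else if (has_timing) {
      tl <- tolower(trimws(as.character(row$metastasis_timing)))
      if (tl %in% timing_levels) timing <- tl
      else issues <- c(issues, sprintf("metastasis_timing '%s' not one of %s",
                                       row$metastasis_timing,
                                       paste(timing_levels, collapse = "/")))
    } else {
      issues <- c(issues, "metastasis timing missing")
    }

    vs <- tolower(trimws(as.character(row$vital_status)))
    if (!vs %in% c("alive", "dead")) {
      issues <- c(issues, sprintf("vital_status '%s' not alive/dead", row$vital_status))
    }

    os <- num(row$os_months)
    if (is.na(os) || os <= 0) issues <- c(issues, "os_months must be a positive number")

    list(
      record = tibble::tibble(
        patient_id = as.character(row$patient_id),
        age_at_diagnosis = age, sex = sex, primary_site = site,
        primary_surgery = surgery, functional = func, ki67_pct = ki67,
        metastasis_timing = timing, well_differentiated = wd,
        stage_iv = s4, vital_status = vs, os_months = os
      ),
      issues = issues
    )
  }

  parsed <- lapply(seq_len(nrow(raw)), parse_row)
  issue_tbl <- purrr::imap_dfr(parsed, function(p, i) {
    if (length(p$issues) == 0) return(NULL)
    tibble::tibble(row = i, patient_id = as.character(raw$patient_id[i]),
                   reason = paste(p$issues, collapse = "; "))
  })
  if (nrow(issue_tbl) == 0) {
    issue_tbl <- tibble::tibble(row = integer(), patient_id = character(),
                                reason = character())
  }
  if (strict && nrow(issue_tbl) > 0) {
    abort_validation("cohort validation failed for %d row(s); first: row %d (%s)",
                     nrow(issue_tbl), issue_tbl$row[1], issue_tbl$reason[1])
  }
  ok <- lengths(lapply(parsed, `[[`, "issues")) == 0
  records <- dplyr::bind_rows(lapply(parsed[ok], `[[`, "record"))
  if (nrow(records) == 0) {
    records <- tibble::tibble(
      patient_id = character(), age_at_diagnosis = numeric(),
      sex = character(), primary_site = character(),
      primary_surgery = logical(), functional = logical(),
      ki67_pct = numeric(), metastasis_timing = character(),
      well_differentiated = logical(), stage_iv = logical(),
      vital_status = character(), os_months = numeric()
    )
  }
  attr(records, "issues") <- issue_tbl
  records
}

#' Validation issues collected while reading a cohort
#'
#' @param cohort A cohort returned by [read_cohort()] or [validate_cohort()].
#' @return Tibble of row numbers, patient ids and reasons.
#' @export
cohort_issues <- function(cohort) {
  attr(cohort, "issues") %||%
    tibble::tibble(row = integer(), patient_id = character(),
                   reason = character())
}

#' Write a cohort CSV
#'
#' Writes the canonical column set; [read_cohort()] of the result
#' round-trips to identical records.
#'
#' @param data Cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  out <- tibble::as_tibble(data)[, cohort_columns()]
  readr::write_csv(out, path)
  invisible(path)
}

#' Cohort summary table
#'
#' Counts and percents per category for sex, primary site, metastasis
#' timing, Ki67 band, functional status, primary surgery and vital status —
#' the standard "general features" table. Percents are integers (rounded
#' half up) by default, matching the usual formatting of such tables.
#'
#' @param data Cohort tibble.
#' @param digits Decimal places of the percent column.
#' @return Tibble: `variable`, `level`, `n`, `pct`.
#' @export
#' @examples
#' summarize_cohort(simulate_cohort(seed = 1))
summarize_cohort <- function(data, digits = 0) {
  n_total <- nrow(data)
  if (n_total == 0) abort_validation("cohort must be nonempty")
  band <- factor(
    ifelse(data$ki67_pct < 3, "0-2",
           ifelse(data$ki67_pct <= 20, "3-20", ">20")),
    levels = c("0-2", "3-20", ">20")
  )
  yn <- function(x, field) {
    factor(ifelse(parse_clinical_logical(x, field), "yes", "no"),
           levels = c("yes", "no"))
  }
  vars <- list(
    sex = factor(data$sex, c("male", "female")),
    primary_site = factor(data$primary_site, c("ileum", "pancreas")),
    metastasis_timing = factor(data$metastasis_timing,
                               c("synchronous", "metachronous_gt24",
                                 "metachronous_le24")),
    ki67_band = band,
    functional = yn(data$functional, "functional"),
    primary_surgery = yn(data$primary_surgery, "primary_surgery"),
    vital_status = factor(data$vital_status, c("alive", "dead"))
  )
  purrr::imap_dfr(vars, function(v, nm) {
    tab <- table(v)
    tibble::tibble(
      variable = nm, level = names(tab), n = as.integer(tab),
      pct = as_percent(as.integer(tab) / n_total, digits)
    )
  })
}

#' Full analysis report for a cohort
#'
#' Orchestrates the whole pipeline: eligibility screen, scoring, score
#' summaries overall / by vital status / by sex, risk-class counts, a
#' threshold scan plus fixed-threshold diagnostics and group death
#' proportions, stratified survival, five-year survival counts, and the
#' within-patient Delta-NEP comparison by vital status. Sections whose test
#' is not computable on the given cohort (e.g. no deaths) are marked so
#' rather than crashing.
#'
#' @param data Cohort tibble (validated; see [read_cohort()]).
#' @param nep_t_thresholds,nep_d_thresholds Fixed cutoffs to evaluate
#'   (defaults: the published 145 for NEP-T; 90 and 116 for NEP-D).
#' @param table Score table.
#' @return An object of class `nep_report`: a named list of section tibbles
#'   and fitted objects, with a `print()` method rendering a text report.
#' @export
#' @examples
#' rep <- full_report(simulate_cohort(seed = 8))
#' names(rep)
full_report <- function(data, nep_t_thresholds = 145,
                        nep_d_thresholds = c(90, 116),
                        table = nep_score_table()) {
  screened <- check_eligibility(data, table)
  eligible <- dplyr::filter(screened, .data$eligible)
  sections <- list(
    eligibility = tibble::tibble(
      n_input = nrow(screened), n_eligible = nrow(eligible),
      n_excluded = sum(!screened$eligible)
    ),
    exclusions = dplyr::filter(screened, !.data$eligible)[
      , c("patient_id", "ineligibility_reasons")]
  )
  if (nrow(eligible) < 2) {
    sections$note <- "fewer than 2 eligible records: analysis sections omitted"
    return(structure(sections, class = "nep_report"))
  }
  scored <- nep_score(eligible, table)
  dead <- is_dead(scored$vital_status)
  sem <- function(x) stats::sd(x) / sqrt(length(x))

  score_summary <- scored |>
    tidyr::pivot_longer(cols = c("nep_d", "nep_t", "delta_nep"),
                        names_to = "score", values_to = "value") |>
    dplyr::group_by(.data$score) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sem = sem(.data$value), .groups = "drop")
  by_status <- scored |>
    tidyr::pivot_longer(cols = c("nep_d", "nep_t", "delta_nep"),
                        names_to = "score", values_to = "value") |>
    dplyr::group_by(.data$score, .data$vital_status) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sem = sem(.data$value), .groups = "drop")
  by_sex <- scored |>
    tidyr::pivot_longer(cols = c("nep_d", "nep_t"),
                        names_to = "score", values_to = "value") |>
    dplyr::group_by(.data$score, .data$sex, .data$vital_status) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sem = sem(.data$value), .groups = "drop")

  sections$scores <- score_summary
  sections$scores_by_status <- by_status
  sections$scores_by_sex <- by_sex
  sections$risk_classes <- scored |>
    dplyr::count(.data$risk_class_t, name = "n") |>
    dplyr::rename(risk_class = "risk_class_t")
  sections$mortality <- overall_mortality(scored)

  both_outcomes <- length(unique(dead)) == 2
  if (both_outcomes) {
    sections$scan_nep_t <- scan_thresholds(scored, score = "nep_t")
    sections$scan_nep_d <- scan_thresholds(scored, score = "nep_d")
    fixed <- function(score, thresholds) {
      purrr::map_dfr(thresholds, function(t) {
        dplyr::bind_cols(
          threshold_diagnostics(scored, t, score = score),
          proportion_dead_by_group(scored, t, score = score)[
            , c("p_dead_high", "p_dead_low", "chi2", "p_value")]
        )
      })
    }
    sections$fixed_nep_t <- fixed("nep_t", nep_t_thresholds)
    sections$fixed_nep_d <- fixed("nep_d", nep_d_thresholds)
    sections$survival_nep_d <- purrr::map(
      rlang::set_names(nep_d_thresholds, paste0("threshold_", nep_d_thresholds)),
      function(t) stratify_survival(scored, t, score = "nep_d")
    )
    sections$five_year <- purrr::map_dfr(nep_d_thresholds, function(t) {
      five_year_survival(scored, t, score = "nep_d")
    })
    sections$delta_by_status <- compare_group_means(
      scored, "delta_nep", group = "vital_status"
    )
    sections$paired_d_vs_t <- compare_group_means(
      scored, "nep_d", value2 = "nep_t", paired = TRUE
    )
  } else {
    sections$note <- paste("all patients share one vital status:",
                           "threshold and survival comparisons not computable")
  }
  structure(sections, class = "nep_report")
}

#' @export
print.nep_report <- function(x, ...) {
  cat("== Cohort analysis report ==\n\n")
  cat(sprintf("Eligibility: %d of %d records eligible (%d excluded)\n",
              x$eligibility$n_eligible, x$eligibility$n_input,
              x$eligibility$n_excluded))
  if (nrow(x$exclusions) > 0) {
    cat("Excluded records:\n")
    print(x$exclusions)
  }
  if (!is.null(x$note)) {
    cat("\nNOTE:", x$note, "\n")
    if (is.null(x$scores)) return(invisible(x))
  }
  cat("\n-- Scores (mean +/- SEM) --\n")
  print(x$scores)
  cat("\n-- By vital status --\n")
  print(x$scores_by_status)
  cat("\n-- Risk classes (NEP-T) --\n")
  print(x$risk_classes)
  cat(sprintf("\nOverall mortality: %d/%d (%.1f%%)\n",
              x$mortality$n_dead, x$mortality$n_total,
              x$mortality$mortality_pct))
  if (!is.null(x$fixed_nep_t)) {
    cat("\n-- Fixed-threshold diagnostics (NEP-T) --\n")
    print(x$fixed_nep_t)
    cat("\n-- Fixed-threshold diagnostics (NEP-D) --\n")
    print(x$fixed_nep_d)
    cat("\n-- Best thresholds --\n")
    print(glance(x$scan_nep_t))
    print(glance(x$scan_nep_d))
    cat("\n-- Five-year survival (NEP-D strata) --\n")
    print(x$five_year)
    cat("\n-- Delta-NEP by vital status --\n")
    print(x$delta_by_status)
  }
  invisible(x)
}
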