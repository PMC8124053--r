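#' The default NEP point table
#'
#' The NEP score adds one point contribution per clinical characteristic:
#' age band at diagnosis, site of the primary tumor, whether the primary was
#' resected, functional (hormone-secreting) status, Ki67 proliferation band,
#' and the timing of metastases relative to diagnosis. The defaults are the
#' published weights; alternative weightings can be loaded from YAML with
#' [read_score_table()] so the calculator itself never changes.
#'
#' Band conventions on the continuous inputs:
#' * age: `< 46` years scores the low band (so an age of exactly 45 scores 0;
#'   the published bands "< 45" / "46-65" leave 45 unassigned and contiguous
#'   integer ages are assumed), `46-65` inclusive the middle band, `> 65` the
#'   high band;
#' * Ki67: `[0, 3)` percent scores 0 (the WHO G1 boundary Ki67 < 3% is
#'   preserved for non-integer values, so 2.5 scores 0), `[3, 20]` scores 12,
#'   `(20, 100]` scores 57.
#'
#' @return A named list with integer point vectors `age`, `site`, `surgery`,
#'   `functional`, `ki67`, `timing`, a character vector `site_aliases`
#'   mapping extra primary sites onto `ileum`/`pancreas` points, and a
#'   `version` string.
#' @export
#' @examples
#' nep_score_table()$timing
nep_score_table <- function() {
  list(
    version = "1.0",
    age = c(under_46 = 0L, from_46_to_65 = 28L, over_65 = 58L),
    site = c(ileum = 0L, pancreas = 59L),
    surgery = c(yes = 0L, no = 100L),
    functional = c(yes = 32L, no = 0L),
    ki67 = c(under_3 = 0L, from_3_to_20 = 12L, over_20 = 57L),
    timing = c(synchronous = 0L, metachronous_gt24 = 38L,
               metachronous_le24 = 72L),
    site_aliases = character()
  )
}

validate_score_table <- function(table) {
  template <- nep_score_table()
  comps <- setdiff(names(template), c("version", "site_aliases"))
  for (comp in comps) {
    got <- table[[comp]]
    want <- template[[comp]]
    if (is.null(got) || !setequal(names(got), names(want))) {
      abort_validation(
        "score table component '%s' must have entries %s", comp,
        paste(names(want), collapse = ", ")
      )
    }
    if (any(is.na(got)) || any(got < 0) || any(got != round(got))) {
      abort_validation("score table component '%s' must be nonnegative integers", comp)
    }
  }
  aliases <- table$site_aliases
  if (length(aliases) > 0) {
    if (is.null(names(aliases)) || any(names(aliases) == "")) {
      abort_validation("site_aliases must be a named character vector")
    }
    bad <- !aliases %in% names(table$site)
    if (any(bad)) {
      abort_validation(
        "site_aliases must map onto %s; offending targets: %s",
        paste(names(table$site), collapse = "/"),
        paste(unique(aliases[bad]), collapse = ", ")
      )
    }
  }
  invisible(table)
}

#' Read or write a score table as YAML
#'
#' The point system ships as a versioned configuration so that refitted
#' weights, or site aliases for cohorts that include e.g. jejunal primaries,
#' can be supplied without code changes. `write_score_table()` followed by
#' `read_score_table()` round-trips exactly.
#'
#' @param path Path to a YAML file.
#' @param table A score table as returned by [nep_score_table()].
#' @return `read_score_table()` returns a validated score table list;
#'   `write_score_table()` returns `path` invisibly.
#' @export
read_score_table <- function(path) {
  raw <- yaml::read_yaml(path)
  template <- nep_score_table()
  out <- template
  out$version <- as.character(raw$version %||% template$version)
  for (comp in c("age", "site", "surgery", "functional", "ki67", "timing")) {
    if (!is.null(raw[[comp]])) {
      v <- unlist(raw[[comp]])
      storage.mode(v) <- "integer"
      out[[comp]] <- v[names(template[[comp]])]
      names(out[[comp]]) <- names(template[[comp]])
    }
  }
  out$site_aliases <- if (length(raw$site_aliases)) unlist(raw$site_aliases) else character()
  validate_score_table(out)
  out
}

#' @rdname read_score_table
#' @export
write_score_table <- function(table, path) {
  validate_score_table(table)
  serial <- lapply(table, function(x) {
    if (is.character(x) && length(x) == 0) return(list())
    as.list(x)
  })
  yaml::write_yaml(serial, path)
  invisible(path)
}
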