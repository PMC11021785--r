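#' Tukey five-number quartiles of onset times
#'
#' Quartiles are Tukey hinges (via [stats::fivenum()]): the medians of the
#' lower and upper halves of the sorted data, each half including the sample
#' median when n is odd. One convention is fixed and documented because
#' printed pharmacovigilance tables rarely state theirs.
#'
#' @param x Numeric vector (no NAs).
#' @return Named numeric vector `q1`, `median`, `q3`.
#' @keywords internal
tukey_quartiles <- function(x) {
  f <- stats::fivenum(x)
  c(q1 = f[2], median = f[3], q3 = f[4])
}

#' Characterise a drug's DILI cohort
#'
#' Builds a descriptive summary over unique retained reports whose
#' primary-suspect drug is `drug` and which carry at least one PT in
#' `dili_pt_set`: counts and percentages for sex, report-year bands,
#' reporter type and outcome; age count/missing/median/quartiles; and the
#' cohort's share of all the drug's reports. Percentages are computed on the
#' cohort size and rounded half-up to 2 decimals; the DILI share of all drug
#' reports is reported at 1 decimal.
#'
#' @param clean A `clean_report_set`.
#' @param drug Drug name.
#' @param dili_pt_set Character vector of PT codes defining the event class.
#' @param synonyms Optional drug-name synonym table.
#' @return A `cohort_summary` list: `drug`, `n_cohort`, `n_drug_reports`,
#'   `dili_pct_of_drug_reports`, `sex`, `age`, `report_year`, `reporter`,
#'   `outcome` tables.
#' @export
summarize_cohort <- function(clean, drug, dili_pt_set, synonyms = NULL) {
  stopifnot(inherits(clean, "clean_report_set"))
  if (length(dili_pt_set) == 0) {
    abort_dilinet("'dili_pt_set' must be nonempty", "dilinet_validation_error")
  }
  ps <- filter_primary_suspect(clean$records, drug, synonyms)
  drug_reports <- unique(ps$report_id)
  cohort_ids <- unique(ps$report_id[ps$pt_code %in% dili_pt_set])
  # one row per report for demographics (fields are constant within a report)
  per_report <- dplyr::slice_head(
    dplyr::group_by(ps[ps$report_id %in% cohort_ids, ], .data$report_id),
    n = 1)
  per_report <- dplyr::ungroup(per_report)
  n <- nrow(per_report)
  if (n == 0) {
    rlang::warn(sprintf("empty cohort for drug '%s'", drug))
  }

  cat_table <- function(x, levels) {
    x <- ifelse(is.na(x) | x == "", "Missing", x)
    counts <- as.integer(table(factor(x, levels = c(levels, "Missing"))))
    pcts <- if (n > 0) pct_of(counts, n, 2) else rep(NA_real_, length(counts))
    tibble::tibble(category = c(levels, "Missing"), n = counts, pct = pcts)
  }
  year_band <- function(y) {
    ifelse(is.na(y), NA_character_,
           ifelse(y <= 2019, "Before 2020", as.character(y)))
  }
  yrs <- sort(unique(per_report$report_year[!is.na(per_report$report_year) &
                                              per_report$report_year > 2019]))
  age_ok <- per_report$age_years[!is.na(per_report$age_years)]
  q <- if (length(age_ok)) tukey_quartiles(age_ok) else
    c(q1 = NA_real_, median = NA_real_, q3 = NA_real_)

  structure(list(
    drug = drug,
    n_cohort = n,
    n_drug_reports = length(drug_reports),
    dili_pct_of_drug_reports = pct_of(n, length(drug_reports), 1),
    sex = cat_table(per_report$sex, c("F", "M")),
    age = list(n = length(age_ok), missing = n - length(age_ok),
               median = unname(q["median"]), q1 = unname(q["q1"]),
               q3 = unname(q["q3"])),
    report_year = cat_table(year_band(per_report$report_year),
                            c("Before 2020", as.character(yrs))),
    reporter = cat_table(per_report$reporter,
                         c("consumer", "health_professional", "unknown")),
    outcome = cat_table(per_report$outcome, OUTCOME_MENU)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %s: %d DILI reports of %d drug reports (%.1f%%)\n",
              x$drug, x$n_cohort, x$n_drug_reports,
              x$dili_pct_of_drug_reports))
  invisible(x)
}

#' Time-to-onset summary for a drug's event cohort
#'
#' Onset is `event_onset_date - therapy_start_date` in whole days, over
#' unique retained reports with a primary-suspect assertion of the drug and
#' at least one PT in `dili_pt_set`. Reports with either date missing, or a
#' negative difference (a data-quality failure, excluded rather than
#' clamped), count as missing. Quartiles are Tukey hinges.
#'
#' @inheritParams summarize_cohort
#' @return An `onset_summary` list: `n`, `missing`, `median`, `q1`, `q3`.
#' @export
time_to_onset <- function(clean, drug, dili_pt_set, synonyms = NULL) {
  stopifnot(inherits(clean, "clean_report_set"))
  ps <- filter_primary_suspect(clean$records, drug, synonyms)
  cohort_ids <- unique(ps$report_id[ps$pt_code %in% dili_pt_set])
  per_report <- dplyr::ungroup(dplyr::slice_head(
    dplyr::group_by(ps[ps$report_id %in% cohort_ids, ], .data$report_id),
    n = 1))
  n_total <- nrow(per_report)
  start <- as.Date(ifelse(per_report$therapy_start_date == "", NA,
                          per_report$therapy_start_date))
  onset <- as.Date(ifelse(per_report$event_onset_date == "", NA,
                          per_report$event_onset_date))
  days <- as.numeric(onset - start)
  neg <- sum(!is.na(days) & days < 0)
  if (neg > 0) {
    rlang::warn(sprintf("excluded %d report(s) with negative time-to-onset",
                        neg))
  }
  days <- days[!is.na(days) & days >= 0]
  q <- if (length(days)) tukey_quartiles(days) else
    c(q1 = NA_real_, median = NA_real_, q3 = NA_real_)
  structure(list(n = length(days), missing = n_total - length(days),
                 median = unname(q["median"]), q1 = unname(q["q1"]),
                 q3 = unname(q["q3"])),
            class = "onset_summary")
}

#' @export
print.onset_summary <- function(x, ...) {
  cat(sprintf("<onset_summary> n=%d (missing %d), median %s days (q1 %s, q3 %s)\n",
              x$n, x$missing, format(x$median), format(x$q1), format(x$q3)))
  invisible(x)
}
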