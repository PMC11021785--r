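REPORT_COLUMNS <- c("report_id", "case_id", "case_version", "receipt_date",
                    "drug_name", "drug_role", "pt_code", "sex", "age_years",
                    "report_year", "reporter", "outcome",
                    "therapy_start_date", "event_onset_date")

OUTCOME_MENU <- c("Life-Threatening", "Hospitalization", "Disability",
                  "Death", "Other")

#' Read a spontaneous-report table
#'
#' Reads the report CSV dialect (header
#' `report_id,case_id,case_version,receipt_date,drug_name,drug_role,pt_code,`
#' `sex,age_years,report_year,reporter,outcome,therapy_start_date,`
#' `event_onset_date`; UTF-8; empty string = missing). Rows violating record
#' invariants (empty report_id, case_version < 1, unparseable dates, therapy
#' start after event onset) are dropped and reported with their line numbers.
#'
#' @param path CSV file path.
#' @param max_bad_fraction Abort if more than this fraction of data rows is
#'   invalid (default 0.25).
#' @return Tibble of validated report records; attributes `n_read` (data rows
#'   read) and `rejected` (tibble of line numbers and reasons).
#' @export
read_reports <- function(path, max_bad_fraction = 0.25) {
  if (!file.exists(path)) {
    abort_dilinet(sprintf("report file not found: %s", path),
                  "dilinet_io_error")
  }
  x <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                       na = character(), progress = FALSE)
  missing_cols <- setdiff(REPORT_COLUMNS, names(x))
  if (length(missing_cols)) {
    abort_dilinet(
      sprintf("missing mandatory column(s): %s",
              paste(missing_cols, collapse = ", ")),
      "dilinet_schema_error")
  }
  x <- x[REPORT_COLUMNS]
  n_read <- nrow(x)
  if (n_read == 0) {
    out <- tibble::as_tibble(x)
    out$case_version <- integer()
    out$age_years <- numeric()
    out$report_year <- integer()
    attr(out, "n_read") <- 0L
    attr(out, "rejected") <- tibble::tibble(line = integer(),
                                            reason = character())
    return(out)
  }

  ver <- suppressWarnings(as.integer(x$case_version))
  age <- suppressWarnings(as.numeric(ifelse(x$age_years == "", NA,
                                            x$age_years)))
  yr <- suppressWarnings(as.integer(x$report_year))
  parse_date <- function(s) as.Date(ifelse(s == "", NA, s), format = "%Y-%m-%d")
  d_receipt <- parse_date(x$receipt_date)
  d_start <- parse_date(x$therapy_start_date)
  d_onset <- parse_date(x$event_onset_date)

  reason <- rep(NA_character_, n_read)
  flag <- function(bad, why) reason <<- ifelse(is.na(reason) & bad, why, reason)
  flag(x$report_id == "", "empty report_id")
  flag(x$case_id == "", "empty case_id")
  flag(is.na(ver) | ver < 1, "case_version must be an integer >= 1")
  flag(x$pt_code == "", "empty pt_code")
  flag(x$drug_name == "", "empty drug_name")
  flag(x$receipt_date != "" & is.na(d_receipt), "unparseable receipt_date")
  flag(x$therapy_start_date != "" & is.na(d_start),
       "unparseable therapy_start_date")
  flag(x$event_onset_date != "" & is.na(d_onset),
       "unparseable event_onset_date")
  flag(!is.na(d_start) & !is.na(d_onset) & d_start > d_onset,
       "therapy_start_date after event_onset_date")

  bad <- !is.na(reason)
  rejected <- tibble::tibble(line = which(bad) + 1L, reason = reason[bad])
  if (n_read > 0 && sum(bad) / n_read > max_bad_fraction) {
    abort_dilinet(
      sprintf("%d of %d rows invalid (> %.0f%% allowed); first problem: line %d (%s)",
              sum(bad), n_read, 100 * max_bad_fraction,
              rejected$line[1], rejected$reason[1]),
      "dilinet_parse_error")
  }
  out <- tibble::as_tibble(x[!bad, ])
  out$case_version <- ver[!bad]
  out$age_years <- age[!bad]
  out$report_year <- yr[!bad]
  if (nrow(rejected)) {
    rlang::warn(sprintf("dropped %d invalid row(s); lines %s", nrow(rejected),
                        paste(utils::head(rejected$line, 10), collapse = ", ")))
  }
  attr(out, "n_read") <- n_read
  attr(out, "rejected") <- rejected
  out
}

#' Deduplicate report versions to one retained report per case
#'
#' Spontaneous-report databases carry follow-up versions of the same case;
#' counting more than one inflates every frequency downstream. For each
#' `case_id` the rows of a single retained version are kept: the highest
#' `case_version`, ties broken by latest `receipt_date`, then by
#' lexicographically greatest `report_id`. Deterministic and idempotent.
#'
#' @param records Tibble of validated report records.
#' @return A `clean_report_set`: list with `records` (retained rows) and
#'   `counters` (rows_read, rows_dropped_dedup, rows_retained).
#' @export
deduplicate <- function(records) {
  records <- tibble::as_tibble(records)
  n_in <- nrow(records)
  if (n_in == 0) {
    return(new_clean_report_set(records,
                                counters = c(rows_read = 0L,
                                             rows_dropped_dedup = 0L,
                                             rows_retained = 0L)))
  }
  key <- paste(records$case_id, records$case_version, records$receipt_date,
               records$report_id, sep = "\r")
  keys <- records[!duplicated(key),
                  c("case_id", "case_version", "receipt_date", "report_id")]
  ord <- order(keys$case_id,
               -keys$case_version,
               -xtfrm(keys$receipt_date),
               -xtfrm(keys$report_id))
  keys <- keys[ord, ]
  winners <- keys[!duplicated(keys$case_id), ]
  win_key <- paste(winners$case_id, winners$case_version,
                   winners$receipt_date, winners$report_id, sep = "\r")
  kept <- records[key %in% win_key, ]
  new_clean_report_set(
    kept,
    counters = c(rows_read = n_in,
                 rows_dropped_dedup = n_in - nrow(kept),
                 rows_retained = nrow(kept)))
}

new_clean_report_set <- function(records, counters) {
  structure(list(records = tibble::as_tibble(records), counters = counters),
            class = "clean_report_set")
}

#' @export
print.clean_report_set <- function(x, ...) {
  cat(sprintf(
    "<clean_report_set> %d rows retained (%d read, %d dropped as superseded versions); %d cases\n",
    x$counters[["rows_retained"]], x$counters[["rows_read"]],
    x$counters[["rows_dropped_dedup"]], length(unique(x$records$case_id))))
  invisible(x)
}

#' Normalise a drug name
#'
#' Case-folds, trims whitespace, collapses internal runs of whitespace, and
#' maps aliases (brand names, salt forms) through a synonym table.
#'
#' @param x Character vector of drug names.
#' @param synonyms Optional data frame with columns `alias`, `canonical`
#'   (matched after case-folding).
#' @return Normalised character vector.
#' @export
normalize_drug_name <- function(x, synonyms = NULL) {
  z <- tolower(trimws(x))
  z <- gsub("[[:space:]]+", " ", z)
  if (!is.null(synonyms) && nrow(synonyms) > 0) {
    alias <- tolower(trimws(synonyms$alias))
    canonical <- tolower(trimws(synonyms$canonical))
    hit <- match(z, alias)
    z[!is.na(hit)] <- canonical[hit[!is.na(hit)]]
  }
  z
}

#' Keep primary-suspect assertions of one drug
#'
#' Restricts rows to those whose normalised `drug_name` matches the target
#' drug and whose `drug_role` is `PS` (primary suspect). Rows with a role
#' outside the documented menu (PS/SS/C/I) are excluded with a warning.
#'
#' @param records Tibble of report records (or a `clean_report_set`).
#' @param drug Target drug name (normalised internally).
#' @param synonyms Optional synonym table (see [normalize_drug_name()]).
#' @return Tibble of matching rows.
#' @export
filter_primary_suspect <- function(records, drug, synonyms = NULL) {
  if (inherits(records, "clean_report_set")) records <- records$records
  if (length(drug) != 1 || is.na(drug) || !nzchar(drug)) {
    abort_dilinet("'drug' must be a single nonempty string",
                  "dilinet_validation_error")
  }
  bad_role <- !records$drug_role %in% c("PS", "SS", "C", "I")
  if (any(bad_role)) {
    rlang::warn(sprintf("excluded %d row(s) with unknown drug_role code(s): %s",
                        sum(bad_role),
                        paste(unique(records$drug_role[bad_role]),
                              collapse = ", ")))
    records <- records[!bad_role, ]
  }
  target <- normalize_drug_name(drug, synonyms)
  records[normalize_drug_name(records$drug_name, synonyms) == target &
            records$drug_role == "PS", ]
}

#' Cases reporting more than one study drug
#'
#' Diagnostic for multi-drug cases: after deduplication, lists cases with
#' primary-suspect or secondary-suspect assertions of two or more of the
#' study drugs. Such cases are retained in all analyses; this op only
#' surfaces them.
#'
#' @param clean A `clean_report_set`.
#' @param drugs Character vector of study drug names.
#' @param synonyms Optional synonym table.
#' @return Tibble with `case_id` and `n_study_drugs`.
#' @export
multi_drug_cases <- function(clean, drugs, synonyms = NULL) {
  stopifnot(inherits(clean, "clean_report_set"))
  rec <- clean$records
  rec$drug_norm <- normalize_drug_name(rec$drug_name, synonyms)
  targets <- normalize_drug_name(drugs, synonyms)
  rec <- rec[rec$drug_norm %in% targets, ]
  out <- dplyr::summarise(dplyr::group_by(rec, .data$case_id),
                          n_study_drugs = dplyr::n_distinct(.data$drug_norm),
                          .groups = "drop")
  out[out$n_study_drugs >= 2, ]
}
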