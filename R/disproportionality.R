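#' Build the 2x2 contingency table for one drug against an event set
#'
#' Counting is at report level with ANY-match semantics: a retained report is
#' on the "drug" margin if any of its primary-suspect (PS) assertions names
#' the target drug, and on the "event" margin if any of its PTs falls in
#' `pt_set`. The comparator is all other reports in the database, so
#' `a + b + c + d` equals the number of retained reports. ANY-match prevents
#' a single report from being counted once per member PT of an SMQ.
#'
#' @param clean A `clean_report_set` (deduplicated).
#' @param drug Target drug name.
#' @param pt_set Nonempty character vector of PT codes defining the event.
#' @param synonyms Optional drug-name synonym table.
#' @return A `contingency_table`: list with integer cells `a`, `b`, `c`, `d`.
#' @export
#' @examples
#' # a report with the drug and the event, one with each alone, one with
#' # neither -> (1, 1, 1, 1)
build_contingency <- function(clean, drug, pt_set, synonyms = NULL) {
  stopifnot(inherits(clean, "clean_report_set"))
  if (length(pt_set) == 0) {
    abort_dilinet("'pt_set' must be nonempty", "dilinet_validation_error")
  }
  rec <- clean$records
  target <- normalize_drug_name(drug, synonyms)
  rid <- factor(rec$report_id)
  drug_pos <- rowsum(as.integer(
    rec$drug_role == "PS" &
      normalize_drug_name(rec$drug_name, synonyms) == target),
    rid) > 0
  event_pos <- rowsum(as.integer(rec$pt_code %in% pt_set), rid) > 0
  a <- sum(drug_pos & event_pos)
  b <- sum(drug_pos & !event_pos)
  c_ <- sum(!drug_pos & event_pos)
  d <- sum(!drug_pos & !event_pos)
  new_contingency(a, b, c_, d)
}

#' Construct a 2x2 contingency table from its cells
#'
#' @param a Reports with target drug and target event(s).
#' @param b Reports with target drug, other events.
#' @param c Reports with other drugs, target event(s).
#' @param d Reports with other drugs, other events.
#' @return A `contingency_table` object.
#' @export
new_contingency <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0) ||
      any(cells != floor(cells))) {
    abort_dilinet("contingency cells must be nonnegative integers",
                  "dilinet_validation_error")
  }
  structure(lapply(as.list(cells), as.integer), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> a=%d b=%d c=%d d=%d (N=%d)\n",
              x$a, x$b, x$c, x$d, x$a + x$b + x$c + x$d))
  invisible(x)
}

#' Reporting odds ratio with Woolf confidence interval
#'
#' ROR = (a*d)/(b*c); the CI is built on the log scale with standard error
#' `sqrt(1/a + 1/b + 1/c + 1/d)` (Woolf), so the point estimate is the
#' geometric mean of the bounds. If any cell is zero, the Haldane-Anscombe
#' correction adds 0.5 to all four cells before estimation (`corrected`
#' flags this); `n_reports` always carries the raw, uncorrected `a` so the
#' report-count signal criterion is unaffected.
#'
#' @param t A `contingency_table`.
#' @param z Normal quantile for the CI (default 1.96, a 95% interval).
#' @return A `signal_stats` list: `ror`, `ci_low`, `ci_high`, `se_log`,
#'   `n_reports`, `corrected`.
#' @export
#' @examples
#' compute_ror(new_contingency(5, 95, 100, 9900))
compute_ror <- function(t, z = 1.96) {
  stopifnot(inherits(t, "contingency_table"))
  a <- t$a; b <- t$b; c_ <- t$c; d <- t$d
  if (a + b == 0 || c_ + d == 0) {
    abort_dilinet(
      "degenerate margin: drug or comparator has no reports",
      "dilinet_degenerate_margin_error")
  }
  corrected <- any(c(a, b, c_, d) == 0)
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  ror <- (a * d) / (b * c_)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  structure(
    list(ror = ror,
         ci_low = exp(log(ror) - z * se),
         ci_high = exp(log(ror) + z * se),
         se_log = se,
         n_reports = t$a,
         corrected = corrected),
    class = "signal_stats")
}

#' @export
print.signal_stats <- function(x, ...) {
  cat(sprintf("<signal_stats> ROR %.2f (95%% CI %.2f-%.2f), N=%d%s\n",
              round_half_up(x$ror), round_half_up(x$ci_low),
              round_half_up(x$ci_high), x$n_reports,
              if (x$corrected) ", continuity-corrected" else ""))
  invisible(x)
}

#' Apply the positive-signal rule
#'
#' A drug-event pair is a positive signal when it has at least `min_count`
#' reports and the lower bound of the 95% CI of the ROR exceeds 1.
#'
#' @param s A `signal_stats` object.
#' @param min_count Minimum report count (default 3).
#' @return Logical.
#' @export
detect_signal <- function(s, min_count = 3) {
  stopifnot(inherits(s, "signal_stats"))
  s$n_reports >= min_count && s$ci_low > 1
}

#' Scan drug x event-set signals across a dictionary level
#'
#' Expands each requested code through [expand_query()] and computes one
#' signal row per drug x code. Negative results are retained with
#' `positive = FALSE`; pairs with a degenerate margin (drug absent from the
#' database) are reported with NA statistics rather than aborting the scan.
#' No multiplicity adjustment is applied across the scanned grid
#' (disproportionality scans are conventionally reported unadjusted); the
#' output carries `multiplicity_adjusted = FALSE` metadata.
#'
#' @param clean A `clean_report_set`.
#' @param drugs Character vector of drug names.
#' @param dict A `meddra_dict`.
#' @param level `"pt"`, `"hlt"` or `"smq"`.
#' @param codes Codes to scan, or `NULL` for every code at the level.
#' @param scope SMQ scope passed to [expand_query()].
#' @param min_count Signal-rule report-count threshold.
#' @param z Normal quantile for the CI.
#' @param synonyms Optional drug-name synonym table.
#' @return Tibble with one row per drug x code: drug, level, code, name, n,
#'   ror, ci_low, ci_high, se_log, corrected, positive — sorted by HLT name
#'   then term name within each drug at PT level, by name otherwise.
#' @export
scan_signals <- function(clean, drugs, dict, level = c("pt", "hlt", "smq"),
                         codes = NULL, scope = c("combined", "narrow"),
                         min_count = 3, z = 1.96, synonyms = NULL) {
  stopifnot(inherits(clean, "clean_report_set"), inherits(dict, "meddra_dict"))
  level <- match.arg(level)
  scope <- match.arg(scope)
  if (is.null(codes)) {
    codes <- switch(level,
                    pt = dict$pts$pt_code,
                    hlt = dict$hlts$hlt_code,
                    smq = union(dict$smqs$smq_code,
                                dict$smq_children$parent_code))
  }
  name_of <- function(code) {
    switch(level,
           pt = dict$pts$pt_name[match(code, dict$pts$pt_code)],
           hlt = dict$hlts$hlt_name[match(code, dict$hlts$hlt_code)],
           smq = {
             nm <- dict$smqs$smq_name[match(code, dict$smqs$smq_code)]
             if (is.na(nm)) paste0(code, " (comprehensive)") else nm
           })
  }
  grid <- expand.grid(drug = drugs, code = codes, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    drug <- grid$drug[i]; code <- grid$code[i]
    pt_set <- expand_query(dict, level, code, scope)
    tab <- build_contingency(clean, drug, pt_set, synonyms)
    stats <- tryCatch(compute_ror(tab, z = z),
                      dilinet_degenerate_margin_error = function(e) NULL)
    tibble::tibble(
      drug = drug, level = level, code = code, name = name_of(code),
      n = tab$a,
      ror = if (is.null(stats)) NA_real_ else stats$ror,
      ci_low = if (is.null(stats)) NA_real_ else stats$ci_low,
      ci_high = if (is.null(stats)) NA_real_ else stats$ci_high,
      se_log = if (is.null(stats)) NA_real_ else stats$se_log,
      corrected = if (is.null(stats)) NA else stats$corrected,
      positive = if (is.null(stats)) FALSE else detect_signal(stats, min_count))
  })
  out <- dplyr::bind_rows(rows)
  if (level == "pt") {
    out$hlt_name <- dict$hlts$hlt_name[
      match(dict$pts$hlt_code[match(out$code, dict$pts$pt_code)],
            dict$hlts$hlt_code)]
    out <- dplyr::arrange(out, .data$drug, .data$hlt_name, .data$name)
    out <- dplyr::relocate(out, "hlt_name", .after = "code")
  } else {
    out <- dplyr::arrange(out, .data$drug, .data$name)
  }
  attr(out, "multiplicity_adjusted") <- FALSE
  out
}

#' Write a signal scan to CSV
#'
#' Full-precision statistics plus display-rounded twins (`ror_2dp`,
#' `ci_low_2dp`, `ci_high_2dp`; half-up to 2 decimals, the conventional
#' table format).
#'
#' @param scan Tibble from [scan_signals()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_signals <- function(scan, path) {
  scan$ror_2dp <- round_half_up(scan$ror, 2)
  scan$ci_low_2dp <- round_half_up(scan$ci_low, 2)
  scan$ci_high_2dp <- round_half_up(scan$ci_high, 2)
  readr::write_csv(scan, path, progress = FALSE)
  invisible(path)
}
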