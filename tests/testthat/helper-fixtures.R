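# In-code fixtures shared across test files.

# A minimal validated report-record tibble; every field defaults sensibly so
# tests state only what they care about.
make_records <- function(report_id, case_id = report_id, case_version = 1L,
                         receipt_date = "2020-06-01", drug_name = "drugA",
                         drug_role = "PS", pt_code = "PT001", sex = "F",
                         age_years = 60, report_year = 2020L,
                         reporter = "consumer", outcome = "Other",
                         therapy_start_date = "2020-01-01",
                         event_onset_date = "2020-02-01") {
  tibble::tibble(report_id = report_id, case_id = case_id,
                 case_version = as.integer(case_version),
                 receipt_date = receipt_date, drug_name = drug_name,
                 drug_role = drug_role, pt_code = pt_code, sex = sex,
                 age_years = age_years, report_year = as.integer(report_year),
                 reporter = reporter, outcome = outcome,
                 therapy_start_date = therapy_start_date,
                 event_onset_date = event_onset_date)
}

# One report = one (report_id, drug, pt) triple here; bind several for richer
# databases.
tiny_dict <- function() {
  new_meddra_dict(
    pts = tibble::tibble(
      pt_code = c("PT001", "PT002", "PT003", "PT004", "PT005"),
      pt_name = c("ALT increased", "Jaundice", "Hepatic failure",
                  "Ascites", "Nausea"),
      hlt_code = c("HLT01", "HLT01", "HLT02", "HLT02", "HLT03")),
    hlts = tibble::tibble(
      hlt_code = c("HLT01", "HLT02", "HLT03"),
      hlt_name = c("Liver investigations", "Hepatic disorders",
                   "GI disorders")),
    smqs = tibble::tibble(
      smq_code = c("SMQ01", "SMQ01", "SMQ02", "SMQ02", "SMQ02"),
      smq_name = c("Liver findings", "Liver findings", "Liver damage",
                   "Liver damage", "Liver damage"),
      pt_code = c("PT001", "PT002", "PT002", "PT003", "PT004"),
      scope = c("narrow", "broad", "narrow", "narrow", "broad")),
    smq_children = tibble::tibble(parent_code = "SMQ00",
                                  child_code = c("SMQ01", "SMQ02")))
}

# Cached fixture bundle: built once per test run, read-only thereafter.
fixture_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "dilinet-fixture-bundle")
      cache <<- make_fixture_bundle(dir, seed = 1)
    }
    cache
  }
})
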