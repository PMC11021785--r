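test_that("contingency counting is report-level with ANY-match semantics", {
  # exhaustive toy: one report in each cell of the 2x2
  recs <- dplyr::bind_rows(
    make_records("R1", drug_name = "drugA", pt_code = "PT001"),
    make_records("R2", drug_name = "drugA", pt_code = "PT999"),
    make_records("R3", drug_name = "drugB", pt_code = "PT001"),
    make_records("R4", drug_name = "drugB", pt_code = "PT999"))
  t <- build_contingency(deduplicate(recs), "drugA", "PT001")
  expect_identical(unclass(t)[c("a", "b", "c", "d")],
                   list(a = 1L, b = 1L, c = 1L, d = 1L))

  # a report with two member PTs of the set counts once (ANY-match)
  recs2 <- dplyr::bind_rows(
    make_records(c("R1", "R1"), pt_code = c("PT001", "PT002")),
    make_records("R2", drug_name = "drugB", pt_code = "PT999"))
  t2 <- build_contingency(deduplicate(recs2), "drugA", c("PT001", "PT002"))
  expect_identical(t2$a, 1L)

  expect_error(build_contingency(deduplicate(recs), "drugA", character()),
               class = "dilinet_validation_error")
})

test_that("hand-labelled 40-report database matches brute-force enumeration", {
  set.seed(77)
  drugs <- sample(c("drugA", "drugB", "drugC"), 40, replace = TRUE)
  pts <- sample(sprintf("PT%03d", 1:4), 40, replace = TRUE)
  recs <- make_records(sprintf("R%02d", 1:40), drug_name = drugs,
                       pt_code = pts)
  clean <- deduplicate(recs)
  pt_set <- c("PT001", "PT002")
  t <- build_contingency(clean, "drugA", pt_set)
  # oracle: explicit loop over reports
  a <- b <- c_ <- d <- 0L
  for (i in 1:40) {
    dpos <- drugs[i] == "drugA"
    epos <- pts[i] %in% pt_set
    if (dpos && epos) a <- a + 1L else if (dpos) b <- b + 1L
    else if (epos) c_ <- c_ + 1L else d <- d + 1L
  }
  expect_identical(unclass(t)[c("a", "b", "c", "d")],
                   list(a = a, b = b, c = c_, d = d))
  expect_identical(t$a + t$b + t$c + t$d, 40L)
})

test_that("ROR and Woolf CI reproduce the closed form at extended precision", {
  s <- compute_ror(new_contingency(5, 95, 100, 9900))
  expect_equal(s$ror, 5.210526, tolerance = 1e-6)
  expect_equal(s$se_log, 0.469710, tolerance = 1e-6)
  expect_equal(s$ci_low, 2.075184, tolerance = 1e-6)
  expect_equal(s$ci_high, 13.082980, tolerance = 1e-6)
  expect_false(s$corrected)
  expect_identical(s$n_reports, 5L)

  sym <- compute_ror(new_contingency(10, 10, 10, 10))
  expect_equal(sym$ror, 1.0)
  expect_true(sym$ci_low < 1 && sym$ci_high > 1)
})

test_that("zero cells trigger the Haldane-Anscombe correction; margins error", {
  s <- compute_ror(new_contingency(0, 20, 10, 100))
  expect_true(s$corrected)
  expect_identical(s$n_reports, 0L)
  expect_true(is.finite(s$ror) && s$ror > 0 && is.finite(s$ci_low))
  expect_error(compute_ror(new_contingency(0, 0, 10, 100)),
               class = "dilinet_degenerate_margin_error")
  expect_error(compute_ror(new_contingency(10, 100, 0, 0)),
               class = "dilinet_degenerate_margin_error")
})

test_that("Woolf geometry: point estimate is the geometric mean of the bounds", {
  set.seed(5)
  for (i in 1:50) {
    cells <- sample(1:500, 4, replace = TRUE)
    s <- compute_ror(new_contingency(cells[1], cells[2], cells[3], cells[4]))
    expect_true(s$ci_low <= s$ror && s$ror <= s$ci_high)
    expect_equal(exp((log(s$ci_low) + log(s$ci_high)) / 2), s$ror,
                 tolerance = 1e-12)
  }
})

test_that("antisymmetry: swapping the drug margin inverts the ROR and CI", {
  set.seed(9)
  for (i in 1:25) {
    cells <- sample(1:200, 4, replace = TRUE)
    s <- compute_ror(new_contingency(cells[1], cells[2], cells[3], cells[4]))
    r <- compute_ror(new_contingency(cells[2], cells[1], cells[4], cells[3]))
    expect_equal(r$ror, 1 / s$ror, tolerance = 1e-12)
    expect_equal(r$ci_low, 1 / s$ci_high, tolerance = 1e-12)
    expect_equal(r$ci_high, 1 / s$ci_low, tolerance = 1e-12)
  }
})

test_that("ROR equals the sample odds ratio on all small tables", {
  for (a in 1:6) for (b in 1:6) for (c_ in 1:6) for (d in 1:6) {
    s <- compute_ror(new_contingency(a, b, c_, d))
    expect_equal(s$ror, oracle_odds_ratio(a, b, c_, d), tolerance = 1e-12)
  }
})

test_that("95% CI covers a true odds ratio of 2 at the nominal rate", {
  # multinomial sampling with cell probabilities engineered to OR = 2
  probs <- c(2, 10, 10, 100) / 122
  stopifnot(abs(oracle_odds_ratio(probs[1], probs[2], probs[3], probs[4]) - 2)
            < 1e-12)
  set.seed(2024)
  draws <- stats::rmultinom(1000, size = 2000, prob = probs)
  covered <- vapply(seq_len(ncol(draws)), function(j) {
    x <- draws[, j]
    if (any(x[1] + x[2] == 0 | x[3] + x[4] == 0)) return(NA)
    s <- compute_ror(new_contingency(x[1], x[2], x[3], x[4]))
    s$ci_low <= 2 && 2 <= s$ci_high
  }, logical(1))
  rate <- mean(covered, na.rm = TRUE)
  expect_gte(rate, 0.93)
  expect_lte(rate, 0.97)
})

test_that("the signal rule requires both the count and the CI criterion", {
  stats_of <- function(n, lo) structure(
    list(ror = lo * 1.5, ci_low = lo, ci_high = lo * 2.25, se_log = 0.2,
         n_reports = n, corrected = FALSE), class = "signal_stats")
  expect_true(detect_signal(stats_of(3, 1.05)))
  expect_false(detect_signal(stats_of(2, 8.0)))
  expect_false(detect_signal(stats_of(3, 1.0)))
  expect_true(detect_signal(stats_of(3, 1.05), min_count = 3))
  expect_false(detect_signal(stats_of(5, 1.05), min_count = 6))
  # a large-count pair whose CI sits below 1 is not a signal
  no_signal <- structure(
    list(ror = 0.70, ci_low = 0.67, ci_high = 0.73, se_log = 0.02,
         n_reports = 2256, corrected = FALSE), class = "signal_stats")
  expect_false(detect_signal(no_signal))
})

test_that("signal scans recover the planted pair and respect expansion identities", {
  paths <- fixture_bundle()
  dict <- load_dictionary(paths$dict)
  clean <- deduplicate(read_reports(paths$reports))
  drugs <- c("palbociclib", "ribociclib", "abemaciclib")

  scan_pt <- scan_signals(clean, drugs, dict, level = "pt",
                          codes = sprintf("PT%03d", 1:12))
  expect_identical(nrow(scan_pt), 36L)
  planted <- scan_pt[scan_pt$drug == "ribociclib" & scan_pt$code == "PT001", ]
  expect_true(planted$positive)
  expect_gt(planted$ror, 1.5)
  # the planted pair is the strongest positive in the grid (fixed seed)
  positives <- scan_pt[scan_pt$positive, ]
  expect_identical(positives$code[which.max(positives$n)], "PT001")

  # scanning a comprehensive SMQ equals scanning its union PT set
  scan_smq <- scan_signals(clean, "ribociclib", dict, level = "smq",
                           codes = "SMQ100")
  manual <- compute_ror(build_contingency(
    clean, "ribociclib", expand_query(dict, "smq", "SMQ100")))
  expect_equal(scan_smq$ror, manual$ror, tolerance = 1e-12)
  expect_identical(scan_smq$n, manual$n_reports)

  # a drug absent from the database yields NA stats without aborting the scan
  scan_ghost <- scan_signals(clean, c("ribociclib", "ghostdrug"), dict,
                             level = "smq", codes = "SMQ100")
  expect_true(is.na(scan_ghost$ror[scan_ghost$drug == "ghostdrug"]))
  expect_false(scan_ghost$positive[scan_ghost$drug == "ghostdrug"])
  expect_false(is.na(scan_ghost$ror[scan_ghost$drug == "ribociclib"]))
})

test_that("an all-null small database produces no positives at fixed seed", {
  cfg <- sim_config(n_cases = 300, drugs = c(drugA = 0.15, drugB = 0.15),
                    events = c(PT001 = 0.03, PT002 = 0.03), seed = 314)
  sim <- simulate_database(cfg)
  clean <- deduplicate(sim$reports)
  dict <- new_meddra_dict(
    pts = tibble::tibble(pt_code = c("PT001", "PT002"),
                         pt_name = c("A", "B"), hlt_code = "HLT01"),
    hlts = tibble::tibble(hlt_code = "HLT01", hlt_name = "H"),
    smqs = tibble::tibble(smq_code = character(), smq_name = character(),
                          pt_code = character(), scope = character()))
  scan <- scan_signals(clean, c("drugA", "drugB"), dict, level = "pt")
  expect_identical(sum(scan$positive), 0L)
})
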