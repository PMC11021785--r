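#' Simulation configuration for a synthetic spontaneous-report database
#'
#' Defines the generative model for a FAERS-like database of adverse-event
#' reports with known ground truth. Event occurrence follows a logistic-odds
#' model: each monitored event has baseline odds `p/(1-p)`, multiplied by the
#' planted odds multiplier `omega` of every exposed drug that carries one, so
#' the reporting odds ratio is the estimand the generator plants.
#'
#' @param n_cases Number of distinct cases (patients) to simulate.
#' @param drugs Named numeric vector: drug name -> exposure probability in (0,1).
#' @param events Named numeric vector: monitored PT code -> baseline event
#'   probability in (0,1).
#' @param planted_or Data frame with columns `drug`, `pt_code`, `omega`
#'   (odds multiplier > 0). Pairs not listed default to omega = 1.
#' @param duplicate_fraction Fraction of cases re-emitted as a follow-up
#'   version, in `[0,1)`.
#' @param multi_drug_probability Probability that a case receives one extra
#'   study drug beyond its sampled exposures, in `[0,1)`.
#' @param missing_age_fraction,missing_sex_fraction,missing_onset_fraction
#'   Missingness fractions in `[0,1)`.
#' @param onset_median_days Named numeric vector of per-drug median
#'   time-to-onset in days (or a single number recycled to all drugs).
#' @param background_pts Character vector of filler PT codes; every report
#'   carries one background event so that reports without a monitored event
#'   still enter the database (a spontaneous report always reports something).
#' @param seed Integer seed; identical config + seed gives byte-identical output.
#' @return An object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(
#'   n_cases = 500,
#'   drugs = c(drugA = 0.1, drugB = 0.1),
#'   events = c(PT001 = 0.02),
#'   planted_or = data.frame(drug = "drugA", pt_code = "PT001", omega = 4),
#'   seed = 1
#' )
sim_config <- function(n_cases,
                       drugs,
                       events,
                       planted_or = NULL,
                       duplicate_fraction = 0.1,
                       multi_drug_probability = 0.02,
                       missing_age_fraction = 0.2,
                       missing_sex_fraction = 0.07,
                       missing_onset_fraction = 0.6,
                       onset_median_days = 40,
                       background_pts = sprintf("PTBG%02d", 1:8),
                       seed = 1L) {
  if (!is.numeric(n_cases) || length(n_cases) != 1 || n_cases < 1 ||
      n_cases != floor(n_cases)) {
    abort_dilinet("invalid value for 'n_cases': must be a positive integer",
                  "dilinet_validation_error")
  }
  if (length(drugs) == 0 || is.null(names(drugs)) || any(names(drugs) == "")) {
    abort_dilinet("invalid value for 'drugs': need a named vector of >= 1 drug",
                  "dilinet_validation_error")
  }
  if (length(events) == 0 || is.null(names(events)) || any(names(events) == "")) {
    abort_dilinet("invalid value for 'events': need a named vector of >= 1 event",
                  "dilinet_validation_error")
  }
  for (d in names(drugs)) check_prob(drugs[[d]], paste0("drugs[", d, "]"),
                                     lower_open = TRUE, upper_open = TRUE)
  for (e in names(events)) check_prob(events[[e]], paste0("events[", e, "]"),
                                      lower_open = TRUE, upper_open = TRUE)
  check_prob(duplicate_fraction, "duplicate_fraction", upper_open = TRUE)
  check_prob(multi_drug_probability, "multi_drug_probability", upper_open = TRUE)
  check_prob(missing_age_fraction, "missing_age_fraction", upper_open = TRUE)
  check_prob(missing_sex_fraction, "missing_sex_fraction", upper_open = TRUE)
  check_prob(missing_onset_fraction, "missing_onset_fraction", upper_open = TRUE)

  if (is.null(planted_or)) {
    planted_or <- data.frame(drug = character(), pt_code = character(),
                             omega = numeric())
  }
  if (!all(c("drug", "pt_code", "omega") %in% names(planted_or))) {
    abort_dilinet(
      "invalid value for 'planted_or': need columns drug, pt_code, omega",
      "dilinet_validation_error")
  }
  if (nrow(planted_or) > 0) {
    if (any(!is.finite(planted_or$omega)) || any(planted_or$omega <= 0)) {
      abort_dilinet("invalid value for 'planted_or': omega must be > 0",
                    "dilinet_validation_error")
    }
    bad_d <- setdiff(planted_or$drug, names(drugs))
    bad_e <- setdiff(planted_or$pt_code, names(events))
    if (length(bad_d) || length(bad_e)) {
      abort_dilinet(
        sprintf("invalid value for 'planted_or': unknown %s",
                paste(c(if (length(bad_d)) paste0("drug ", bad_d),
                        if (length(bad_e)) paste0("pt_code ", bad_e)),
                      collapse = "; ")),
        "dilinet_validation_error")
    }
  }

  if (length(onset_median_days) == 1 && is.null(names(onset_median_days))) {
    onset_median_days <- stats::setNames(rep(onset_median_days, length(drugs)),
                                         names(drugs))
  }
  if (!all(names(drugs) %in% names(onset_median_days)) ||
      any(!is.finite(onset_median_days)) || any(onset_median_days <= 0)) {
    abort_dilinet(
      "invalid value for 'onset_median_days': need a positive value per drug",
      "dilinet_validation_error")
  }
  if (length(background_pts) < 1) {
    abort_dilinet("invalid value for 'background_pts': need >= 1 filler PT",
                  "dilinet_validation_error")
  }

  structure(
    list(n_cases = as.integer(n_cases), drugs = drugs, events = events,
         planted_or = tibble::as_tibble(planted_or),
         duplicate_fraction = duplicate_fraction,
         multi_drug_probability = multi_drug_probability,
         missing_age_fraction = missing_age_fraction,
         missing_sex_fraction = missing_sex_fraction,
         missing_onset_fraction = missing_onset_fraction,
         onset_median_days = onset_median_days[names(drugs)],
         background_pts = as.character(background_pts),
         seed = as.integer(seed)),
    class = "sim_config")
}

# Run code with a locally-seeded RNG, restoring global .Random.seed after.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a spontaneous-report database with planted disproportionality
#'
#' Generates one report table in the package's report CSV dialect together
#' with its ground truth. Per case: exposure to each drug is drawn
#' independently from its exposure probability (cases with no exposure are
#' assigned one drug, weighted by exposure probability; an extra drug is added
#' with `multi_drug_probability`); one exposed drug is designated primary
#' suspect (PS), the rest are secondary/concomitant. Each monitored event
#' occurs with odds = baseline odds x the product of planted multipliers over
#' exposed drugs; every report additionally carries one background PT. A
#' `duplicate_fraction` of cases is re-emitted as version-2 follow-ups.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `reports` (tibble, one row per
#'   report-drug-event assertion) and `truth` (list: `planted_or`, `exposure`
#'   logical matrix, `events` logical matrix of monitored events, `ps_drug`
#'   per case, `duplicates` named list case_id -> report_ids).
#' @export
simulate_database <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort_dilinet("'config' must be a sim_config object",
                  "dilinet_validation_error")
  }
  with_local_seed(config$seed, simulate_database_impl(config))
}

simulate_database_impl <- function(config) {
  n <- config$n_cases
  drug_names <- names(config$drugs)
  nd <- length(drug_names)
  ev_codes_all <- names(config$events)
  ne <- length(ev_codes_all)

  ## exposure matrix, >=1 drug forced, optional extra drug
  E <- matrix(stats::runif(n * nd) < rep(config$drugs, each = n), nrow = n)
  none <- which(rowSums(E) == 0)
  if (length(none)) {
    pick <- sample.int(nd, length(none), replace = TRUE,
                       prob = config$drugs / sum(config$drugs))
    E[cbind(none, pick)] <- TRUE
  }
  extra <- which(stats::runif(n) < config$multi_drug_probability &
                   rowSums(E) < nd)
  if (length(extra) && nd > 1) {
    pick <- vapply(extra, function(i) {
      cand <- which(!E[i, ])
      cand[sample.int(length(cand), 1)]
    }, integer(1))
    E[cbind(extra, pick)] <- TRUE
  }

  ## monitored events: logistic odds with planted multipliers
  base_odds <- config$events / (1 - config$events)
  W <- matrix(0, nrow = nd, ncol = ne,
              dimnames = list(drug_names, ev_codes_all)) # log omega
  if (nrow(config$planted_or) > 0) {
    W[cbind(match(config$planted_or$drug, drug_names),
            match(config$planted_or$pt_code, ev_codes_all))] <-
      log(config$planted_or$omega)
  }
  log_odds <- matrix(rep(log(base_odds), each = n), nrow = n) + E %*% W
  p_event <- 1 / (1 + exp(-log_odds))
  M <- matrix(stats::runif(n * ne) < p_event, nrow = n,
              dimnames = list(NULL, ev_codes_all))

  ## primary suspect: among exposed drugs, weighted by each drug's planted
  ## odds contribution to the events that occurred (reporter suspicion
  ## tracks the likely culprit); uniform when nothing distinguishes them
  suspicion <- exp(M %*% t(W))
  ps_idx <- vapply(seq_len(n), function(i) {
    w <- which(E[i, ])
    w[sample.int(length(w), 1, prob = suspicion[i, w])]
  }, integer(1))
  ps_drug <- drug_names[ps_idx]

  ## one background PT per case
  filler <- config$background_pts[
    sample.int(length(config$background_pts), n, replace = TRUE)]

  ## demographics (menus mirror the usual spontaneous-report categories)
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.92, 0.08))
  sex[stats::runif(n) < config$missing_sex_fraction] <- ""
  age <- round(pmin(pmax(stats::rnorm(n, 60, 11), 18), 95))
  age[stats::runif(n) < config$missing_age_fraction] <- NA_real_
  reporter <- sample(c("consumer", "health_professional", "unknown"), n,
                     replace = TRUE, prob = c(0.40, 0.55, 0.05))
  outcome <- sample(c("Life-Threatening", "Hospitalization", "Disability",
                      "Death", "Other", ""), n, replace = TRUE,
                    prob = c(0.04, 0.27, 0.01, 0.16, 0.32, 0.20))

  ## dates: therapy start uniform over the study window, onset log-normal
  ## with the PS drug's configured median (sdlog 1 gives FAERS-like right skew)
  start <- as.Date("2014-01-01") +
    floor(stats::runif(n) * as.numeric(as.Date("2022-12-31") -
                                         as.Date("2014-01-01")))
  onset_days <- stats::rlnorm(n,
                              meanlog = log(config$onset_median_days[ps_drug]),
                              sdlog = 1)
  onset <- start + round(onset_days)
  receipt <- onset + floor(stats::runif(n, 0, 61))
  onset_missing <- stats::runif(n) < config$missing_onset_fraction

  ## per-case drug assertions (sorted by case, then drug index)
  dr_pairs <- which(E, arr.ind = TRUE)
  dr_pairs <- dr_pairs[order(dr_pairs[, 1], dr_pairs[, 2]), , drop = FALSE]
  dr_case <- dr_pairs[, 1]
  dr_code <- drug_names[dr_pairs[, 2]]
  role <- ifelse(dr_pairs[, 2] == ps_idx[dr_case], "PS",
                 sample(c("SS", "C", "I"), nrow(dr_pairs), replace = TRUE,
                        prob = c(0.5, 0.4, 0.1)))
  dc <- tabulate(dr_case, nbins = n)

  ## per-case event codes: monitored events that fired, plus the filler PT
  ev_pairs <- which(M, arr.ind = TRUE)
  ev_case <- c(ev_pairs[, 1], seq_len(n))
  ev_code <- c(ev_codes_all[ev_pairs[, 2]], filler)
  o <- order(ev_case)
  ev_split <- split(ev_code[o], factor(ev_case[o], levels = seq_len(n)))
  ec <- lengths(ev_split)

  ## expand to one row per (case, drug, event)
  row_case <- rep(dr_case, ec[dr_case])
  row_drug <- rep(dr_code, ec[dr_case])
  row_role <- rep(role, ec[dr_case])
  row_pt <- unlist(rep(ev_split, dc), use.names = FALSE)

  case_id <- sprintf("C%06d", seq_len(n))
  fmt <- function(d, drop) {
    s <- format(d, "%Y-%m-%d")
    s[drop] <- ""
    s
  }
  build_rows <- function(version, cases_mask, receipt_shift) {
    keep <- cases_mask[row_case]
    i <- row_case[keep]
    tibble::tibble(
      report_id = sprintf("%s-%d", case_id[i], version),
      case_id = case_id[i],
      case_version = version,
      receipt_date = format(receipt[i] + receipt_shift, "%Y-%m-%d"),
      drug_name = row_drug[keep],
      drug_role = row_role[keep],
      pt_code = row_pt[keep],
      sex = sex[i],
      age_years = age[i],
      report_year = as.integer(format(receipt[i] + receipt_shift, "%Y")),
      reporter = reporter[i],
      outcome = outcome[i],
      therapy_start_date = fmt(start[i], onset_missing[i]),
      event_onset_date = fmt(onset[i], onset_missing[i])
    )
  }

  all_cases <- rep(TRUE, n)
  v1 <- build_rows(1L, all_cases, 0)
  n_dup <- floor(config$duplicate_fraction * n)
  dup_cases <- sort(sample.int(n, n_dup))
  dup_mask <- rep(FALSE, n)
  dup_mask[dup_cases] <- TRUE
  v2 <- build_rows(2L, dup_mask, 30)
  reports <- dplyr::arrange(dplyr::bind_rows(v1, v2),
                            .data$case_id, .data$case_version)

  duplicates <- stats::setNames(
    lapply(dup_cases, function(i) sprintf("%s-%d", case_id[i], 1:2)),
    case_id[dup_cases])

  truth <- list(
    planted_or = config$planted_or,
    exposure = `dimnames<-`(E, list(case_id, drug_names)),
    events = `rownames<-`(M, case_id),
    ps_drug = stats::setNames(ps_drug, case_id),
    duplicates = duplicates
  )
  list(reports = reports, truth = truth)
}
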