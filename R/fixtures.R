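# Fixed fixture vocabularies. Gene symbols are real human gene names (the
# hub genes any liver-injury network analysis would surface) but the lists
# themselves are synthetic conventions, not database exports.
FIXTURE_DRUGS <- c(palbociclib = 0.25, ribociclib = 0.25, abemaciclib = 0.20)

FIXTURE_PTS <- tibble::tibble(
  pt_code = sprintf("PT%03d", 1:12),
  pt_name = c("Alanine aminotransferase increased",
              "Aspartate aminotransferase increased",
              "Blood bilirubin increased",
              "Gamma-glutamyltransferase increased",
              "Hepatic enzyme increased",
              "Liver function test increased",
              "Hepatic failure",
              "Hepatic cirrhosis",
              "Hepatotoxicity",
              "Drug-induced liver injury",
              "Jaundice",
              "Ascites"),
  hlt_code = c("HLT01", "HLT01", "HLT01", "HLT01", "HLT01", "HLT01",
               "HLT02", "HLT02", "HLT03", "HLT03", "HLT04", "HLT04"))

FIXTURE_BG_PTS <- tibble::tibble(
  pt_code = sprintf("PTBG%02d", 1:8),
  pt_name = c("Nausea", "Fatigue", "Neutropenia", "Diarrhoea", "Alopecia",
              "Headache", "Rash", "Arthralgia"),
  hlt_code = "HLT99")

FIXTURE_HLTS <- tibble::tibble(
  hlt_code = c("HLT01", "HLT02", "HLT03", "HLT04", "HLT99"),
  hlt_name = c("Hepatobiliary function diagnostic procedures",
               "Hepatic failure and associated disorders",
               "Hepatocellular damage and hepatitis NEC",
               "Hepatobiliary signs and symptoms",
               "General and administration-site conditions"))

# two leaf SMQs with narrow/broad scopes, one comprehensive parent over both
FIXTURE_SMQS <- tibble::tibble(
  smq_code = c(rep("SMQ101", 6), rep("SMQ102", 6)),
  smq_name = c(rep("Liver related investigations, signs and symptoms", 6),
               rep("Hepatic failure, fibrosis and other liver damage", 6)),
  pt_code = sprintf("PT%03d", 1:12),
  scope = c("narrow", "narrow", "narrow", "broad", "narrow", "broad",
            "narrow", "narrow", "narrow", "narrow", "broad", "broad"))

FIXTURE_SMQ_CHILDREN <- tibble::tibble(
  parent_code = "SMQ100",
  child_code = c("SMQ101", "SMQ102"))

FIXTURE_TARGET_GENES <- c(
  "CDK4", "CDK6", "CCND1", "STAT3", "HSP90AA1", "EP300", "HIF1A", "ESR1",
  "PIK3CA", "NFKB1", "STAT1", "PIK3R1", "CREBBP", "SIRT1", "PPARG", "RB1",
  "CCNE1", "CDKN2A", "MYC", "AKT1", "MTOR", "EGFR", "ERBB2", "AURKA",
  "PLK1", "WEE1", "CHEK1", "ABCB1", "CYP3A4", "ALB")

FIXTURE_DISEASE_GENES <- c(
  "STAT3", "HSP90AA1", "EP300", "HIF1A", "ESR1", "PIK3CA", "NFKB1", "STAT1",
  "PIK3R1", "CREBBP", "SIRT1", "PPARG", "ALB", "CYP3A4", "CYP2E1", "GPT",
  "GOT1", "TNF", "IL6", "TGFB1", "NFE2L2", "KEAP1", "HMOX1", "SOD1", "CAT",
  "GSTP1", "UGT1A1", "SLCO1B1", "ABCC2", "BSEP", "NR1H4", "FGF21", "CASP3",
  "BAX", "BCL2", "TP53", "MAPK1", "MAPK8", "JUN", "FOS")

FIXTURE_PATHWAYS <- list(
  PW001 = list(name = "JAK-STAT signaling",
               members = c("STAT3", "STAT1", "IL6", "PIK3CA", "PIK3R1",
                           "AKT1", "MYC", "CCND1")),
  PW002 = list(name = "PI3K-Akt signaling",
               members = c("PIK3CA", "PIK3R1", "AKT1", "MTOR", "NFKB1",
                           "TP53", "BCL2", "CCND1", "HSP90AA1")),
  PW003 = list(name = "Cellular senescence",
               members = c("CDK4", "CDK6", "CCND1", "CCNE1", "RB1",
                           "CDKN2A", "TP53", "MYC", "MAPK1")),
  PW004 = list(name = "Hepatic xenobiotic metabolism",
               members = c("CYP3A4", "CYP2E1", "GSTP1", "UGT1A1", "NR1H4",
                           "ABCC2", "SLCO1B1", "HMOX1")),
  PW005 = list(name = "Apoptosis",
               members = c("CASP3", "BAX", "BCL2", "TP53", "JUN", "FOS",
                           "MAPK8", "NFKB1", "TNF")),
  PW006 = list(name = "HIF-1 signaling",
               members = c("HIF1A", "EP300", "CREBBP", "STAT3", "AKT1",
                           "MTOR", "NFKB1")))

#' Default fixture simulation configuration
#'
#' The study conditions the fixture bundle emulates: three study drugs with
#' one planted signal (ribociclib x "Alanine aminotransferase increased",
#' odds multiplier 4), moderate baseline event rates, 10% duplicated cases
#' and Table-3-like missingness.
#'
#' @param n_cases Number of cases (default 600).
#' @param seed Seed.
#' @return A [sim_config()] object.
#' @export
fixture_sim_config <- function(n_cases = 600, seed = 1L) {
  sim_config(
    n_cases = n_cases,
    drugs = FIXTURE_DRUGS,
    events = stats::setNames(rep(0.03, 12), FIXTURE_PTS$pt_code),
    planted_or = data.frame(drug = "ribociclib", pt_code = "PT001",
                            omega = 4),
    duplicate_fraction = 0.10,
    multi_drug_probability = 0.02,
    missing_age_fraction = 0.20,
    missing_sex_fraction = 0.07,
    missing_onset_fraction = 0.60,
    onset_median_days = c(palbociclib = 48, ribociclib = 42,
                          abemaciclib = 32),
    seed = seed)
}

#' Standard calibration scenarios for the signal-detection pipeline
#'
#' Two fixed simulation scenarios used to calibrate the ROR signal rule:
#' `"null"` — two drugs (10% exposure each), one monitored event at 2%
#' baseline probability, no planted association, 2,000 cases — measures the
#' false-positive rate of the rule (nominally ~2.5% one-sided plus the
#' report-count criterion's slack); `"planted"` — the same database with an
#' odds multiplier of 4 planted on (drugA, PT001) and 5,000 cases — measures
#' CI coverage of the planted odds ratio. The scenario parameters are fixed
#' conventions of the package; only the seed varies across replicates.
#'
#' @param type `"null"` or `"planted"`.
#' @param seed Integer seed.
#' @return A [sim_config()] object.
#' @export
calibration_config <- function(type = c("null", "planted"), seed = 1L) {
  type <- match.arg(type)
  sim_config(
    n_cases = if (type == "null") 2000L else 5000L,
    drugs = c(drugA = 0.1, drugB = 0.1),
    events = c(PT001 = 0.02),
    planted_or = if (type == "planted") {
      data.frame(drug = "drugA", pt_code = "PT001", omega = 4)
    },
    duplicate_fraction = 0.10,
    multi_drug_probability = 0.02,
    missing_age_fraction = 0.20,
    missing_sex_fraction = 0.07,
    missing_onset_fraction = 0.60,
    onset_median_days = 40,
    seed = seed)
}

#' Estimate the ROR for the monitored calibration pair
#'
#' Convenience wrapper running one calibration replicate end to end:
#' simulate, deduplicate, build the (drugA, PT001) contingency table and
#' compute the ROR with its Woolf CI.
#'
#' @param config A [sim_config()] (typically from [calibration_config()]).
#' @param drug,pt_code Monitored pair (defaults drugA / PT001).
#' @return A `signal_stats` object.
#' @export
calibration_replicate <- function(config, drug = "drugA",
                                  pt_code = "PT001") {
  sim <- simulate_database(config)
  clean <- deduplicate(sim$reports)
  compute_ror(build_contingency(clean, drug, pt_code))
}

#' Write a self-consistent fixture bundle
#'
#' Produces everything one pipeline run needs, with all codes and symbols
#' cross-resolving: `reports.csv` (simulated database, planted ground truth
#' in `truth.json`), a dictionary directory `dict/`, `targets.txt`,
#' `disease_genes.txt` (overlap by construction), `string_edges.tsv`
#' (0-1000 integer scores), `pathways.gmt` and `synonyms.csv`. Deterministic
#' in `seed`.
#'
#' @param dir Destination directory (created if needed).
#' @param seed Integer seed.
#' @param n_cases Cases in the simulated database.
#' @return Named list of written paths, invisibly.
#' @export
make_fixture_bundle <- function(dir, seed = 1L, n_cases = 600) {
  ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) {
    abort_dilinet(sprintf("cannot create bundle directory: %s", dir),
                  "dilinet_io_error")
  }
  dict_dir <- file.path(dir, "dict")
  dir.create(dict_dir, showWarnings = FALSE)

  sim <- simulate_database(fixture_sim_config(n_cases = n_cases, seed = seed))
  paths <- list(
    reports = file.path(dir, "reports.csv"),
    truth = file.path(dir, "truth.json"),
    dict = dict_dir,
    targets = file.path(dir, "targets.txt"),
    disease = file.path(dir, "disease_genes.txt"),
    edges = file.path(dir, "string_edges.tsv"),
    gmt = file.path(dir, "pathways.gmt"),
    synonyms = file.path(dir, "synonyms.csv"))

  readr::write_csv(sim$reports, paths$reports, progress = FALSE)
  jsonlite::write_json(
    list(planted_or = sim$truth$planted_or,
         ps_drug = as.list(sim$truth$ps_drug),
         duplicates = sim$truth$duplicates),
    paths$truth, auto_unbox = TRUE, pretty = TRUE)

  readr::write_csv(dplyr::bind_rows(FIXTURE_PTS, FIXTURE_BG_PTS),
                   file.path(dict_dir, "pt.csv"), progress = FALSE)
  readr::write_csv(FIXTURE_HLTS, file.path(dict_dir, "hlt.csv"),
                   progress = FALSE)
  readr::write_csv(FIXTURE_SMQS, file.path(dict_dir, "smq.csv"),
                   progress = FALSE)
  readr::write_csv(FIXTURE_SMQ_CHILDREN,
                   file.path(dict_dir, "smq_children.csv"), progress = FALSE)

  readr::write_lines(FIXTURE_TARGET_GENES, paths$targets)
  readr::write_lines(FIXTURE_DISEASE_GENES, paths$disease)

  # seeded random PPI edges over the target/disease intersection plus a few
  # disease-only genes; STRING-style 0-1000 integer scores
  inter <- intersect(FIXTURE_TARGET_GENES, FIXTURE_DISEASE_GENES)
  pool <- sort(union(inter, c("TP53", "IL6", "TNF", "CASP3", "BCL2")))
  edges <- with_local_seed(seed + 1000L, {
    all_pairs <- t(utils::combn(pool, 2))
    keep <- stats::runif(nrow(all_pairs)) < 0.35
    tibble::tibble(
      protein1 = all_pairs[keep, 1],
      protein2 = all_pairs[keep, 2],
      combined_score = sample(150:999, sum(keep), replace = TRUE))
  })
  utils::write.table(edges, paths$edges, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  gmt_lines <- vapply(names(FIXTURE_PATHWAYS), function(id) {
    paste(c(id, FIXTURE_PATHWAYS[[id]]$name,
            FIXTURE_PATHWAYS[[id]]$members), collapse = "\t")
  }, "")
  readr::write_lines(gmt_lines, paths$gmt)

  readr::write_csv(
    tibble::tibble(alias = c("KISQALI", "IBRANCE", "VERZENIO",
                             "palbociclib isethionate"),
                   canonical = c("ribociclib", "palbociclib", "abemaciclib",
                                 "palbociclib")),
    paths$synonyms, progress = FALSE)

  invisible(paths)
}
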