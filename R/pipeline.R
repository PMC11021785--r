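#' Build a pipeline run configuration
#'
#' Collects every input path and threshold of the end-to-end study replica.
#' All referenced files must exist at construction time; thresholds are
#' validated against their documented ranges.
#'
#' @param reports Report CSV path.
#' @param dict_dir Dictionary directory ([load_dictionary()] dialect).
#' @param drugs Character vector of study drugs.
#' @param smq_code SMQ defining the event class under study.
#' @param targets_file,disease_file Gene lists (one symbol per line).
#' @param edges_file PPI edge list ([read_ppi_edges()] dialect).
#' @param gmt_file Pathway collection (GMT).
#' @param out_dir Output directory.
#' @param synonyms_file Optional drug-name synonym CSV (`alias,canonical`).
#' @param scope SMQ scope, `"combined"` or `"narrow"`.
#' @param min_count Signal-rule report threshold (>= 1).
#' @param min_score PPI score threshold in `[0,1]`.
#' @param top_k Hubs to export (>= 1).
#' @param top_pathways Enrichment rows to keep (>= 1).
#' @param seed Integer seed recorded in the manifest.
#' @return A `run_config` object.
#' @export
run_config <- function(reports, dict_dir, drugs, smq_code,
                       targets_file, disease_file, edges_file, gmt_file,
                       out_dir, synonyms_file = NULL,
                       scope = "combined", min_count = 3, min_score = 0.7,
                       top_k = 10, top_pathways = 20, seed = 1L) {
  cfg <- list(reports = reports, dict_dir = dict_dir, drugs = drugs,
              smq_code = smq_code, targets_file = targets_file,
              disease_file = disease_file, edges_file = edges_file,
              gmt_file = gmt_file, out_dir = out_dir,
              synonyms_file = synonyms_file, scope = scope,
              min_count = as.integer(min_count),
              min_score = as.numeric(min_score),
              top_k = as.integer(top_k),
              top_pathways = as.integer(top_pathways),
              seed = as.integer(seed))
  files <- c(reports = reports, targets_file = targets_file,
             disease_file = disease_file, edges_file = edges_file,
             gmt_file = gmt_file, synonyms_file = synonyms_file)
  missing <- files[!vapply(files, file.exists, TRUE)]
  if (!dir.exists(dict_dir)) {
    missing <- c(missing, dict_dir = dict_dir)
  }
  if (length(missing)) {
    abort_dilinet(
      sprintf("missing input(s): %s",
              paste(sprintf("%s (%s)", names(missing), missing),
                    collapse = "; ")),
      "dilinet_config_error")
  }
  if (min_count < 1 || top_k < 1 || top_pathways < 1) {
    abort_dilinet("min_count, top_k and top_pathways must be >= 1",
                  "dilinet_config_error")
  }
  check_prob(min_score, "min_score")
  if (!scope %in% c("combined", "narrow")) {
    abort_dilinet("scope must be 'combined' or 'narrow'",
                  "dilinet_config_error")
  }
  structure(cfg, class = "run_config")
}

#' Load a pipeline configuration from JSON
#'
#' @param path JSON file whose keys match the arguments of [run_config()].
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort_dilinet(sprintf("config file not found: %s", path),
                  "dilinet_config_error")
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort_dilinet(sprintf("unknown config key(s): %s",
                          paste(unknown, collapse = ", ")),
                  "dilinet_config_error")
  }
  do.call(run_config, raw)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort_dilinet(sprintf("stage '%s' failed: %s", stage,
                          conditionMessage(e)),
                  "dilinet_stage_error")
  })
}

#' Run the end-to-end study replica
#'
#' Executes, in order: report reading, case deduplication, signal scans at
#' SMQ, HLT and PT levels, per-drug cohort characterisation with
#' time-to-onset, gene-set intersection, thresholded PPI network with hub
#' ranking, and pathway over-representation. Every stage output is written
#' under `out_dir`, and a machine-readable manifest (config echo, per-stage
#' row counts, timings, MD5 checksums of every output) closes the run. A
#' stage failure aborts with a stage-named error and leaves prior outputs in
#' place. Fully deterministic: same config and inputs give byte-identical
#' outputs.
#'
#' @param cfg A `run_config` (or path to a JSON config).
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  t0 <- Sys.time()
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  counts <- list()
  clock <- function(stage, expr) {
    s <- Sys.time()
    out <- run_stage(stage, expr)
    timings[[stage]] <<- round(as.numeric(Sys.time() - s, units = "secs"), 3)
    out
  }

  synonyms <- if (!is.null(cfg$synonyms_file)) {
    readr::read_csv(cfg$synonyms_file, col_types = "cc", progress = FALSE)
  }
  dict <- clock("dictionary", load_dictionary(cfg$dict_dir))
  records <- clock("read_reports", read_reports(cfg$reports))
  counts$rows_read <- attr(records, "n_read")
  counts$rows_rejected <- nrow(attr(records, "rejected"))
  clean <- clock("deduplicate", deduplicate(records))
  counts <- c(counts, as.list(clean$counters))

  dili_pts <- expand_query(dict, "smq", cfg$smq_code, cfg$scope)
  outputs <- character()
  emit <- function(path) outputs <<- c(outputs, path)

  for (level in c("smq", "hlt", "pt")) {
    scan <- clock(paste0("signals_", level),
                  scan_signals(clean, cfg$drugs, dict, level = level,
                               scope = cfg$scope, min_count = cfg$min_count,
                               synonyms = synonyms))
    counts[[paste0("signals_", level, "_rows")]] <- nrow(scan)
    emit(write_signals(scan,
                       file.path(cfg$out_dir,
                                 sprintf("signals_%s.csv", level))))
  }

  descr <- clock("descriptive", {
    lapply(stats::setNames(cfg$drugs, cfg$drugs), function(d) {
      cs <- suppressWarnings(summarize_cohort(clean, d, dili_pts, synonyms))
      tto <- suppressWarnings(time_to_onset(clean, d, dili_pts, synonyms))
      list(cohort = unclass(cs), time_to_onset = unclass(tto))
    })
  })
  p <- file.path(cfg$out_dir, "descriptive.json")
  jsonlite::write_json(descr, p, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  emit(p)

  net <- clock("network", {
    targets <- read_gene_list(cfg$targets_file, label = "drug_targets")
    disease <- read_gene_list(cfg$disease_file, label = "disease_genes")
    inter <- intersect_gene_sets(targets, disease)
    edges <- read_ppi_edges(cfg$edges_file)
    list(inter = inter, n_targets = length(targets$symbols),
         n_disease = length(disease$symbols),
         net = build_network(inter, edges, min_score = cfg$min_score))
  })
  counts$n_target_genes <- net$n_targets
  counts$n_disease_genes <- net$n_disease
  counts$n_intersection_genes <- length(net$inter$symbols)
  net_dir <- file.path(cfg$out_dir, "network")
  for (f in write_network(net$net, net_dir, top = cfg$top_k)) emit(f)
  p <- file.path(cfg$out_dir, "intersection_genes.txt")
  readr::write_lines(net$inter$symbols, p)
  emit(p)

  enr <- clock("enrichment", {
    coll <- read_gmt(cfg$gmt_file)
    enrich(net$inter, coll, top = cfg$top_pathways)
  })
  counts$n_pathways_tested <- nrow(enr)
  for (f in write_enrichment(enr, file.path(cfg$out_dir, "enrichment"))) {
    emit(f)
  }

  manifest <- list(
    tool = "dilinet",
    version = as.character(utils::packageVersion("dilinet")),
    config = unclass(cfg),
    counts = counts,
    timings_sec = timings,
    total_sec = round(as.numeric(Sys.time() - t0, units = "secs"), 3),
    outputs = lapply(stats::setNames(outputs, ifelse(
      startsWith(outputs, paste0(cfg$out_dir, "/")),
      substring(outputs, nchar(cfg$out_dir) + 2), outputs)),
      function(f) list(path = f, md5 = unname(tools::md5sum(f)))))
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
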