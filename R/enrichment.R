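#' Read a GMT pathway collection
#'
#' Standard GMT: one tab-separated line per gene set — id, description, then
#' member symbols. Members are normalised (trim, uppercase) and deduplicated
#' within each set. The default test universe is the union of all members.
#'
#' @param path GMT file.
#' @return A `pathway_collection`: list with `pathways` (tibble: id, name,
#'   members list-column, size) and `universe` (character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    abort_dilinet(sprintf("GMT file not found: %s", path), "dilinet_io_error")
  }
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[lines != ""]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short)) {
    abort_dilinet(
      sprintf("GMT line %s has fewer than 3 fields",
              paste(short, collapse = ", ")),
      "dilinet_parse_error")
  }
  pathways <- tibble::tibble(
    id = vapply(parts, `[[`, "", 1),
    name = vapply(parts, `[[`, "", 2),
    members = lapply(parts, function(p) {
      m <- toupper(trimws(p[-(1:2)]))
      unique(m[m != ""])
    }))
  pathways$size <- lengths(pathways$members)
  new_pathway_collection(pathways)
}

new_pathway_collection <- function(pathways, universe = NULL) {
  if (is.null(universe)) {
    universe <- sort(unique(unlist(pathways$members)))
  }
  structure(list(pathways = pathways, universe = universe),
            class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("<pathway_collection> %d pathways, universe of %d genes\n",
              nrow(x$pathways), length(x$universe)))
  invisible(x)
}

#' Write a pathway collection back to GMT
#'
#' @param coll A `pathway_collection`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(coll, path) {
  stopifnot(inherits(coll, "pathway_collection"))
  lines <- vapply(seq_len(nrow(coll$pathways)), function(i) {
    paste(c(coll$pathways$id[i], coll$pathways$name[i],
            coll$pathways$members[[i]]), collapse = "\t")
  }, "")
  readr::write_lines(lines, path)
  invisible(path)
}

#' Upper-tail hypergeometric p-value for gene-set overlap
#'
#' P(X >= k) where X counts query genes falling in a pathway of size K when
#' n genes are drawn without replacement from a universe of size N.
#' Evaluated with [stats::phyper()] (log-space-stable); k = 0 returns 1
#' because the upper tail then covers the whole support.
#'
#' @param overlap Observed overlap k.
#' @param query Query size n.
#' @param pathway Pathway size K.
#' @param universe Universe size N.
#' @return p in (0, 1].
#' @export
#' @examples
#' hypergeom_pvalue(3, 5, 5, 20) # 1126/15504
hypergeom_pvalue <- function(overlap, query, pathway, universe) {
  k <- overlap; n <- query; K <- pathway; N <- universe
  if (any(c(k, n, K, N) < 0) || K > N || n > N || k > min(n, K)) {
    abort_dilinet(
      "impossible configuration: need 0 <= overlap <= min(query, pathway) and pathway, query <= universe",
      "dilinet_validation_error")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, returned in input order; validates the input
#' domain (p in (0,1]).
#'
#' @param p_values Numeric vector of raw p-values.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric())
  if (any(!is.finite(p_values)) || any(p_values <= 0 | p_values > 1)) {
    abort_dilinet("p-values must lie in (0, 1]", "dilinet_validation_error")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Hypergeometric over-representation analysis of a gene set
#'
#' Tests the query against every pathway with at least one member in the
#' universe (one-sided, over-representation only). The query is first
#' restricted to the universe (the restriction count is recorded); BH
#' adjustment runs across all tested pathways before truncation. Results are
#' sorted by adjusted p ascending, ties by overlap descending then pathway
#' name, and truncated to `top` rows.
#'
#' @param query A `gene_set`.
#' @param coll A `pathway_collection`.
#' @param top Number of rows to return (default 20); `Inf` for all.
#' @param adjust Apply BH adjustment (default TRUE; with FALSE, `p_adjusted`
#'   equals the raw p).
#' @param min_set,max_set Pathway-size filter applied before testing
#'   (defaults 1 and `Inf`).
#' @return Tibble with pathway id, name, overlap_count, query_size,
#'   pathway_size, universe_size, gene_ratio, p_value, p_adjusted and the
#'   overlapping symbols (list-column); attribute `n_query_dropped` counts
#'   query genes outside the universe.
#' @export
enrich <- function(query, coll, top = 20, adjust = TRUE,
                   min_set = 1, max_set = Inf) {
  stopifnot(inherits(query, "gene_set"), inherits(coll, "pathway_collection"))
  q <- intersect(query$symbols, coll$universe)
  dropped <- length(query$symbols) - length(q)
  if (length(q) == 0) {
    abort_dilinet(
      "query has no genes in the pathway universe; check symbol conventions of query and collection",
      "dilinet_validation_error")
  }
  pw <- coll$pathways
  pw$size_in_universe <- vapply(
    pw$members, function(m) length(intersect(m, coll$universe)), 0L)
  pw <- pw[pw$size_in_universe >= max(1, min_set) &
             pw$size_in_universe <= max_set, ]
  N <- length(coll$universe)
  n <- length(q)
  if (nrow(pw) == 0) {
    out <- tibble::tibble(
      id = character(), name = character(), overlap_count = integer(),
      query_size = integer(), pathway_size = integer(),
      universe_size = integer(), gene_ratio = numeric(),
      p_value = numeric(), p_adjusted = numeric(), overlap_genes = list())
    attr(out, "n_query_dropped") <- dropped
    return(out)
  }
  rows <- lapply(seq_len(nrow(pw)), function(i) {
    members <- intersect(pw$members[[i]], coll$universe)
    hits <- intersect(q, members)
    k <- length(hits)
    tibble::tibble(
      id = pw$id[i], name = pw$name[i],
      overlap_count = k, query_size = n,
      pathway_size = length(members), universe_size = N,
      gene_ratio = k / n,
      p_value = hypergeom_pvalue(k, n, length(members), N),
      overlap_genes = list(sort(hits)))
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- if (adjust) bh_adjust(out$p_value) else out$p_value
  out <- dplyr::arrange(out, .data$p_adjusted,
                        dplyr::desc(.data$overlap_count), .data$name)
  out <- dplyr::relocate(out, "p_adjusted", .after = "p_value")
  if (is.finite(top)) out <- utils::head(out, top)
  attr(out, "n_query_dropped") <- dropped
  out
}

#' Write enrichment results and bubble-plot data
#'
#' `enrichment.csv` holds every scalar field (overlap genes joined with
#' `;`); `bubble.csv` holds the plotting triplet: x = overlap_count,
#' size = gene_ratio, colour = p_adjusted, one row per pathway.
#'
#' @param results Tibble from [enrich()].
#' @param dir Output directory (created if needed).
#' @return Paths written, invisibly.
#' @export
write_enrichment <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  flat <- results
  flat$overlap_genes <- vapply(results$overlap_genes, paste, "",
                               collapse = ";")
  paths <- file.path(dir, c("enrichment.csv", "bubble.csv"))
  readr::write_csv(flat, paths[1], progress = FALSE)
  readr::write_csv(
    tibble::tibble(pathway = results$name, overlap_count = results$overlap_count,
                   gene_ratio = results$gene_ratio,
                   p_adjusted = results$p_adjusted),
    paths[2], progress = FALSE)
  invisible(paths)
}
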