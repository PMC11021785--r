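#' Read a gene list into a normalised gene set
#'
#' One symbol per line; symbols are trimmed, uppercased, optionally remapped
#' through an alias table, then deduplicated. Duplicate and remapped counts
#' are recorded as attributes.
#'
#' @param path Text file, one gene symbol per line.
#' @param label Label for the set (defaults to the file name).
#' @param aliases Optional data frame with columns `alias`, `canonical`.
#' @return A `gene_set`: list with `label` and sorted character `symbols`;
#'   attributes `n_duplicates`, `n_remapped`.
#' @export
read_gene_list <- function(path, label = basename(path), aliases = NULL) {
  if (!file.exists(path)) {
    abort_dilinet(sprintf("gene list not found: %s", path), "dilinet_io_error")
  }
  lines <- readr::read_lines(path, progress = FALSE)
  gene_set(lines, label = label, aliases = aliases)
}

#' Construct a gene set from symbols
#'
#' @param symbols Character vector of gene symbols (normalised internally).
#' @param label Set label.
#' @param aliases Optional alias table (`alias`, `canonical`).
#' @return A `gene_set` object.
#' @export
gene_set <- function(symbols, label = "gene_set", aliases = NULL) {
  z <- toupper(trimws(symbols))
  z <- z[z != ""]
  n_remapped <- 0L
  if (!is.null(aliases) && nrow(aliases) > 0) {
    hit <- match(z, toupper(trimws(aliases$alias)))
    n_remapped <- sum(!is.na(hit))
    z[!is.na(hit)] <- toupper(trimws(aliases$canonical))[hit[!is.na(hit)]]
  }
  n_dup <- length(z) - length(unique(z))
  if (length(z) == 0) {
    rlang::warn(sprintf("gene set '%s' is empty", label))
  }
  structure(list(label = label, symbols = sort(unique(z))),
            class = "gene_set",
            n_duplicates = n_dup, n_remapped = n_remapped)
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d symbols\n", x$label, length(x$symbols)))
  invisible(x)
}

#' Intersect drug-target and disease gene sets
#'
#' @param drug_targets,disease_genes `gene_set` objects.
#' @return A `gene_set` holding the intersection; commutative.
#' @export
intersect_gene_sets <- function(drug_targets, disease_genes) {
  stopifnot(inherits(drug_targets, "gene_set"),
            inherits(disease_genes, "gene_set"))
  gene_set(intersect(drug_targets$symbols, disease_genes$symbols),
           label = paste(drug_targets$label, disease_genes$label,
                         sep = " & "))
}

#' Read a STRING-style protein-protein interaction edge list
#'
#' Whitespace/tab-separated with header `protein1 protein2 combined_score`.
#' Scores are accepted on either the 0-1 real scale or the 0-1000 integer
#' scale of STRING exports; the scale is auto-detected from the maximum
#' score (overridable) and 0-1000 scores are divided by 1000.
#'
#' @param path Edge list file.
#' @param score_scale `"auto"` (default), `"unit"` (0-1) or `"string"`
#'   (0-1000).
#' @return Tibble with `gene_a`, `gene_b`, `combined_score` in `[0,1]`.
#' @export
read_ppi_edges <- function(path, score_scale = c("auto", "unit", "string")) {
  score_scale <- match.arg(score_scale)
  if (!file.exists(path)) {
    abort_dilinet(sprintf("edge list not found: %s", path), "dilinet_io_error")
  }
  x <- utils::read.table(path, header = TRUE, sep = "",
                         stringsAsFactors = FALSE)
  if (ncol(x) < 3) {
    abort_dilinet("edge list needs columns protein1, protein2, combined_score",
                  "dilinet_parse_error")
  }
  names(x)[1:3] <- c("gene_a", "gene_b", "combined_score")
  score <- suppressWarnings(as.numeric(x$combined_score))
  if (any(is.na(score))) {
    abort_dilinet(sprintf("non-numeric combined_score at data row %s",
                          paste(utils::head(which(is.na(score)), 5),
                                collapse = ", ")),
                  "dilinet_parse_error")
  }
  if (score_scale == "auto") {
    score_scale <- if (max(score) > 1) "string" else "unit"
  }
  if (score_scale == "string") score <- score / 1000
  if (any(score < 0 | score > 1)) {
    abort_dilinet("combined_score outside [0,1] after scale conversion",
                  "dilinet_parse_error")
  }
  tibble::tibble(gene_a = toupper(trimws(x$gene_a)),
                 gene_b = toupper(trimws(x$gene_b)),
                 combined_score = score)
}

#' Build the thresholded PPI network over a gene set
#'
#' Keeps edges whose two endpoints both lie in `genes` and whose combined
#' score is at least `min_score`; self-loops are dropped and duplicate or
#' reversed edges collapse to one edge keeping the maximum score. Nodes are
#' the genes with at least one retained edge; isolated members of `genes`
#' are included only with `keep_isolated = TRUE` (degree 0 carries no
#' centrality signal, so they are excluded from hub ranking by default).
#'
#' @param genes A `gene_set`.
#' @param edges Edge tibble from [read_ppi_edges()] (or equivalent).
#' @param min_score Score threshold in `[0,1]` (default 0.7, the
#'   high-confidence STRING convention).
#' @param keep_isolated Keep zero-degree members of `genes` as nodes.
#' @return A `ppi_network`: list with `graph` (igraph), `nodes` tibble
#'   (gene, degree) and `edges` tibble.
#' @export
build_network <- function(genes, edges, min_score = 0.7,
                          keep_isolated = FALSE) {
  stopifnot(inherits(genes, "gene_set"))
  check_prob(min_score, "min_score")
  e <- tibble::as_tibble(edges)
  e$gene_a <- toupper(trimws(e$gene_a))
  e$gene_b <- toupper(trimws(e$gene_b))
  e <- e[e$gene_a %in% genes$symbols & e$gene_b %in% genes$symbols &
           e$combined_score >= min_score & e$gene_a != e$gene_b, ]
  # canonical orientation, then collapse parallel/reversed edges to max score
  flip <- e$gene_a > e$gene_b
  tmp <- e$gene_a[flip]; e$gene_a[flip] <- e$gene_b[flip]; e$gene_b[flip] <- tmp
  e <- dplyr::summarise(dplyr::group_by(e, .data$gene_a, .data$gene_b),
                        combined_score = max(.data$combined_score),
                        .groups = "drop")
  e <- dplyr::arrange(e, .data$gene_a, .data$gene_b)
  vertices <- if (keep_isolated) genes$symbols else
    sort(unique(c(e$gene_a, e$gene_b)))
  g <- igraph::graph_from_data_frame(
    as.data.frame(e), directed = FALSE,
    vertices = data.frame(name = vertices))
  deg <- igraph::degree(g)
  nodes <- tibble::tibble(gene = names(deg), degree = as.integer(deg))
  nodes <- dplyr::arrange(nodes, dplyr::desc(.data$degree), .data$gene)
  structure(list(graph = g, nodes = nodes, edges = e), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Rank hub genes by degree
#'
#' @param net A `ppi_network`.
#' @param k Number of hubs to return; if larger than the node count, all
#'   nodes are returned with a warning.
#' @return Tibble (gene, degree), degree descending, ties alphabetical.
#' @export
rank_hubs <- function(net, k) {
  stopifnot(inherits(net, "ppi_network"))
  if (!is.numeric(k) || length(k) != 1 || k < 1) {
    abort_dilinet("'k' must be a positive integer", "dilinet_validation_error")
  }
  if (k > nrow(net$nodes)) {
    rlang::warn(sprintf("k = %d exceeds node count %d; returning all nodes",
                        k, nrow(net$nodes)))
    k <- nrow(net$nodes)
  }
  net$nodes[seq_len(k), ]
}

#' Export a network as plain-text files
#'
#' Writes `nodes.csv` (gene, degree), `edges.csv` (gene_a, gene_b,
#' combined_score), `hubs.csv` (top-`top` hubs) and `graph.graphml` for
#' external visualisation tools.
#'
#' @param net A `ppi_network`.
#' @param dir Output directory (created if needed).
#' @param top Number of hubs to export (default 10).
#' @return Character vector of written paths, invisibly.
#' @export
write_network <- function(net, dir, top = 10) {
  stopifnot(inherits(net, "ppi_network"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("nodes.csv", "edges.csv", "hubs.csv",
                            "graph.graphml"))
  readr::write_csv(net$nodes, paths[1], progress = FALSE)
  readr::write_csv(net$edges, paths[2], progress = FALSE)
  readr::write_csv(rank_hubs(net, min(top, max(1, nrow(net$nodes)))),
                   paths[3], progress = FALSE)
  igraph::write_graph(net$graph, paths[4], format = "graphml")
  invisible(paths)
}
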