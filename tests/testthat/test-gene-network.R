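write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".txt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("gene lists are normalised, alias-mapped and deduplicated", {
  gs <- read_gene_list(write_lines_tmp(c("stat3", "STAT3 ", "EP300")))
  expect_identical(gs$symbols, c("EP300", "STAT3"))
  expect_identical(attr(gs, "n_duplicates"), 1L)

  aliases <- tibble::tibble(alias = "TP53BP", canonical = "TP53")
  gs2 <- read_gene_list(write_lines_tmp(c("TP53BP", "STAT3")),
                        aliases = aliases)
  expect_true("TP53" %in% gs2$symbols)
  expect_identical(attr(gs2, "n_remapped"), 1L)

  # 25 lines with 3 duplicates -> 22 unique symbols
  lines <- c(sprintf("GENE%02d", 1:22), "GENE01", "gene02", " GENE03 ")
  gs3 <- read_gene_list(write_lines_tmp(lines))
  expect_identical(length(gs3$symbols), 22L)
  expect_identical(attr(gs3, "n_duplicates"), 3L)

  expect_warning(gene_set(character()), "empty")
  expect_error(read_gene_list(file.path(tempdir(), "no-such-file.txt")),
               class = "dilinet_io_error")
})

test_that("gene-set intersection is commutative and bounded by its inputs", {
  a <- gene_set(c("A", "B", "C"), "a")
  b <- gene_set(c("X", "Y"), "b")
  expect_identical(suppressWarnings(intersect_gene_sets(a, b))$symbols,
                   character())
  expect_identical(intersect_gene_sets(a, a)$symbols, a$symbols)

  set.seed(17)
  overlap <- sprintf("OV%02d", 1:12)
  aa <- gene_set(c(overlap, sprintf("A%02d", 1:18)), "aa") # |A| = 30
  bb <- gene_set(c(overlap, sprintf("B%02d", 1:28)), "bb") # |B| = 40
  inter <- intersect_gene_sets(aa, bb)
  expect_identical(length(inter$symbols), 12L)
  expect_identical(inter$symbols,
                   intersect_gene_sets(bb, aa)$symbols)
  expect_true(all(inter$symbols %in% aa$symbols))
  expect_true(all(inter$symbols %in% bb$symbols))
})

test_that("edge reading auto-detects the STRING 0-1000 score scale", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein1\tprotein2\tcombined_score",
               "STAT3\tEP300\t910", "STAT3\tHSP90AA1\t400"), path)
  e <- read_ppi_edges(path)
  expect_equal(e$combined_score, c(0.910, 0.400))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein1\tprotein2\tcombined_score",
               "STAT3\tEP300\t0.91"), path2)
  expect_equal(read_ppi_edges(path2)$combined_score, 0.91)
  path3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein1\tprotein2\tcombined_score", "A\tB\tnot_a_number"),
             path3)
  expect_error(read_ppi_edges(path3), class = "dilinet_parse_error")
})

test_that("network construction applies the threshold and collapse rules", {
  genes <- gene_set(c("A", "B", "C"))
  edges <- tibble::tibble(gene_a = c("A", "B", "A"),
                          gene_b = c("B", "C", "C"),
                          combined_score = c(0.9, 0.9, 0.5))
  net <- build_network(genes, edges, min_score = 0.7)
  expect_identical(nrow(net$edges), 2L)
  deg <- stats::setNames(net$nodes$degree, net$nodes$gene)
  expect_identical(deg[c("A", "B", "C")], c(A = 1L, B = 2L, C = 1L))

  # duplicate and reversed listings collapse to one edge at the max score
  dup <- tibble::tibble(gene_a = c("A", "B"), gene_b = c("B", "A"),
                        combined_score = c(0.71, 0.93))
  net2 <- build_network(genes, dup)
  expect_identical(nrow(net2$edges), 1L)
  expect_equal(net2$edges$combined_score, 0.93)

  # self-loops are dropped; isolated genes appear only on request
  loops <- tibble::tibble(gene_a = c("A", "A"), gene_b = c("A", "B"),
                          combined_score = c(0.99, 0.8))
  net3 <- build_network(genes, loops)
  expect_identical(sort(net3$nodes$gene), c("A", "B"))
  net4 <- build_network(genes, loops, keep_isolated = TRUE)
  expect_identical(sort(net4$nodes$gene), c("A", "B", "C"))
  expect_identical(net4$nodes$degree[net4$nodes$gene == "C"], 0L)
})

test_that("degree map matches brute-force incidence counts on a random network", {
  set.seed(50)
  genes <- gene_set(sprintf("G%02d", 1:50))
  pairs <- t(utils::combn(genes$symbols, 2))
  keep <- runif(nrow(pairs)) < 0.08
  edges <- tibble::tibble(gene_a = pairs[keep, 1], gene_b = pairs[keep, 2],
                          combined_score = runif(sum(keep), 0.5, 1))
  net <- build_network(genes, edges, min_score = 0.7)
  # oracle: count rows incident to each node among threshold-passing edges
  kept <- edges[edges$combined_score >= 0.7, ]
  for (g in net$nodes$gene) {
    expect_identical(net$nodes$degree[net$nodes$gene == g],
                     as.integer(sum(kept$gene_a == g) +
                                  sum(kept$gene_b == g)))
  }
  # sum of degrees = 2 x edge count
  expect_identical(sum(net$nodes$degree), 2L * nrow(net$edges))
  # raising the threshold never adds edges
  for (thr in c(0.75, 0.8, 0.9)) {
    expect_lte(nrow(build_network(genes, edges, min_score = thr)$edges),
               nrow(net$edges))
  }
})

test_that("hub ranking is degree-descending with alphabetical ties", {
  genes <- gene_set(c("X", sprintf("L%d", 1:5)))
  star <- tibble::tibble(gene_a = "X", gene_b = sprintf("L%d", 1:5),
                         combined_score = 0.9)
  net <- build_network(genes, star)
  top <- rank_hubs(net, 1)
  expect_identical(top$gene, "X")
  expect_identical(top$degree, 5L)

  # two nodes tied at degree 3 -> alphabetical order
  genes2 <- gene_set(c("B", "A", "C", "D", "E"))
  edges2 <- tibble::tibble(
    gene_a = c("A", "A", "A", "B", "B", "B"),
    gene_b = c("C", "D", "E", "C", "D", "E"),
    combined_score = 0.9)
  top2 <- rank_hubs(build_network(genes2, edges2), 2)
  expect_identical(top2$gene, c("A", "B"))

  expect_warning(all_nodes <- rank_hubs(net, 99), "exceeds")
  expect_identical(nrow(all_nodes), nrow(net$nodes))
})

test_that("network exports round-trip through plain-text files", {
  paths <- fixture_bundle()
  inter <- intersect_gene_sets(read_gene_list(paths$targets),
                               read_gene_list(paths$disease))
  net <- build_network(inter, read_ppi_edges(paths$edges))
  out <- withr::local_tempdir()
  files <- write_network(net, out, top = 5)
  expect_true(all(file.exists(files)))
  nodes <- readr::read_csv(file.path(out, "nodes.csv"),
                           col_types = "ci", progress = FALSE)
  expect_identical(nodes$gene, net$nodes$gene)
  hubs <- readr::read_csv(file.path(out, "hubs.csv"),
                          col_types = "ci", progress = FALSE)
  expect_identical(nrow(hubs), 5L)
})
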