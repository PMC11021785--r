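#' Load a PT/HLT/SMQ dictionary from its CSV dialect
#'
#' The dictionary lives in a directory of four UTF-8 CSV files with header
#' rows: `pt.csv` (pt_code,pt_name,hlt_code), `hlt.csv` (hlt_code,hlt_name),
#' `smq.csv` (smq_code,smq_name,pt_code,scope with scope in narrow/broad),
#' and optional `smq_children.csv` (parent_code,child_code) declaring
#' comprehensive SMQs that expand through their children. Codes are exact,
#' case-sensitive identifiers; names are labels only. Every PT belongs to
#' exactly one HLT; SMQ membership is many-to-many over PTs.
#'
#' @param path Directory containing the dictionary CSV files.
#' @return A `meddra_dict` object (list of tibbles `pts`, `hlts`, `smqs`,
#'   `smq_children`).
#' @export
load_dictionary <- function(path) {
  if (!dir.exists(path)) {
    abort_dilinet(sprintf("dictionary directory not found: %s", path),
                  "dilinet_io_error")
  }
  read_part <- function(file, cols) {
    f <- file.path(path, file)
    if (!file.exists(f)) {
      abort_dilinet(sprintf("missing dictionary file: %s", f),
                    "dilinet_io_error")
    }
    x <- readr::read_csv(f, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
    if (!all(cols %in% names(x))) {
      abort_dilinet(
        sprintf("%s: expected columns %s", file, paste(cols, collapse = ", ")),
        "dilinet_parse_error")
    }
    bad <- which(rowSums(is.na(x[cols]) | x[cols] == "") > 0)
    if (length(bad)) {
      abort_dilinet(
        sprintf("%s: malformed row(s) at line %s (empty required field)",
                file, paste(bad + 1, collapse = ", ")),
        "dilinet_parse_error")
    }
    x[cols]
  }
  pts <- read_part("pt.csv", c("pt_code", "pt_name", "hlt_code"))
  hlts <- read_part("hlt.csv", c("hlt_code", "hlt_name"))
  smqs <- read_part("smq.csv", c("smq_code", "smq_name", "pt_code", "scope"))
  children <- if (file.exists(file.path(path, "smq_children.csv"))) {
    read_part("smq_children.csv", c("parent_code", "child_code"))
  } else {
    tibble::tibble(parent_code = character(), child_code = character())
  }
  new_meddra_dict(pts, hlts, smqs, children)
}

#' Construct a dictionary from in-memory tables
#'
#' Programmatic counterpart of [load_dictionary()]; validates referential
#' integrity (unique codes, resolving cross-references).
#'
#' @param pts Tibble with `pt_code`, `pt_name`, `hlt_code`.
#' @param hlts Tibble with `hlt_code`, `hlt_name`.
#' @param smqs Tibble with `smq_code`, `smq_name`, `pt_code`, `scope`.
#' @param smq_children Tibble with `parent_code`, `child_code` (may be empty).
#' @return A `meddra_dict` object.
#' @export
new_meddra_dict <- function(pts, hlts, smqs,
                            smq_children = tibble::tibble(
                              parent_code = character(),
                              child_code = character())) {
  pts <- tibble::as_tibble(pts)
  hlts <- tibble::as_tibble(hlts)
  smqs <- tibble::as_tibble(smqs)
  smq_children <- tibble::as_tibble(smq_children)

  if (anyDuplicated(pts$pt_code)) {
    abort_dilinet(
      sprintf("duplicated pt_code: %s",
              paste(unique(pts$pt_code[duplicated(pts$pt_code)]),
                    collapse = ", ")),
      "dilinet_integrity_error")
  }
  if (anyDuplicated(hlts$hlt_code)) {
    abort_dilinet("duplicated hlt_code", "dilinet_integrity_error")
  }
  dangling <- setdiff(pts$hlt_code, hlts$hlt_code)
  if (length(dangling)) {
    abort_dilinet(
      sprintf("pt.csv references unknown hlt_code: %s",
              paste(dangling, collapse = ", ")),
      "dilinet_integrity_error")
  }
  bad_scope <- setdiff(unique(smqs$scope), c("narrow", "broad"))
  if (length(bad_scope)) {
    abort_dilinet(
      sprintf("smq scope must be narrow or broad, got: %s",
              paste(bad_scope, collapse = ", ")),
      "dilinet_integrity_error")
  }
  dangling_pt <- setdiff(smqs$pt_code, pts$pt_code)
  if (length(dangling_pt)) {
    abort_dilinet(
      sprintf("smq.csv references unknown pt_code: %s",
              paste(dangling_pt, collapse = ", ")),
      "dilinet_integrity_error")
  }
  all_smq <- union(smqs$smq_code, smq_children$parent_code)
  dangling_child <- setdiff(smq_children$child_code, all_smq)
  if (length(dangling_child)) {
    abort_dilinet(
      sprintf("smq_children.csv references unknown child smq: %s",
              paste(dangling_child, collapse = ", ")),
      "dilinet_integrity_error")
  }

  structure(list(pts = pts, hlts = hlts, smqs = smqs,
                 smq_children = smq_children),
            class = "meddra_dict")
}

#' @export
print.meddra_dict <- function(x, ...) {
  cat(sprintf(
    "<meddra_dict> %d PTs, %d HLTs, %d SMQs (%d comprehensive)\n",
    nrow(x$pts), nrow(x$hlts), length(unique(x$smqs$smq_code)),
    length(unique(x$smq_children$parent_code))))
  invisible(x)
}

#' Expand a dictionary query to its member preferred terms
#'
#' Queries are expanded at one of three levels: a PT code expands to itself;
#' an HLT code expands to all PTs under it; an SMQ code expands to its member
#' PTs filtered by scope (`narrow` keeps narrow-scope members only,
#' `combined` keeps all). A comprehensive SMQ (one with children declared in
#' `smq_children`) expands through its children with set union.
#'
#' @param dict A `meddra_dict`.
#' @param level One of `"pt"`, `"hlt"`, `"smq"`.
#' @param code Code to expand (exact, case-sensitive match).
#' @param scope `"combined"` (default) or `"narrow"`; only used at SMQ level.
#' @return Character vector of PT codes (sorted, unique).
#' @export
#' @examples
#' dict <- new_meddra_dict(
#'   pts = tibble::tibble(pt_code = c("PT001", "PT002"),
#'                        pt_name = c("ALT increased", "Jaundice"),
#'                        hlt_code = c("HLT01", "HLT01")),
#'   hlts = tibble::tibble(hlt_code = "HLT01", hlt_name = "Liver findings"),
#'   smqs = tibble::tibble(smq_code = "SMQ01", smq_name = "Hepatic disorders",
#'                         pt_code = c("PT001", "PT002"),
#'                         scope = c("narrow", "broad")))
#' expand_query(dict, "smq", "SMQ01", scope = "narrow")
expand_query <- function(dict, level = c("pt", "hlt", "smq"), code,
                         scope = c("combined", "narrow")) {
  stopifnot(inherits(dict, "meddra_dict"))
  level <- match.arg(level)
  scope <- match.arg(scope)
  if (length(code) != 1 || is.na(code) || code == "") {
    abort_dilinet("'code' must be a single nonempty string",
                  "dilinet_lookup_error")
  }
  res <- switch(level,
    pt = {
      if (!code %in% dict$pts$pt_code) lookup_fail(level, code)
      code
    },
    hlt = {
      if (!code %in% dict$hlts$hlt_code) lookup_fail(level, code)
      dict$pts$pt_code[dict$pts$hlt_code == code]
    },
    smq = expand_smq(dict, code, scope, seen = character())
  )
  sort(unique(res))
}

lookup_fail <- function(level, code) {
  abort_dilinet(sprintf("unknown %s code: %s", level, code),
                "dilinet_lookup_error")
}

expand_smq <- function(dict, code, scope, seen) {
  if (code %in% seen) return(character()) # guard against cyclic declarations
  is_parent <- code %in% dict$smq_children$parent_code
  is_leaf <- code %in% dict$smqs$smq_code
  if (!is_parent && !is_leaf) lookup_fail("smq", code)
  own <- if (is_leaf) {
    m <- dict$smqs[dict$smqs$smq_code == code, ]
    if (scope == "narrow") m <- m[m$scope == "narrow", ]
    m$pt_code
  } else character()
  kids <- dict$smq_children$child_code[dict$smq_children$parent_code == code]
  unique(c(own, unlist(lapply(
    kids, expand_smq, dict = dict, scope = scope, seen = c(seen, code)))))
}
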