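# Independent oracles, coded from first principles and kept free of any
# package internals so they can arbitrate against the implementation.

# Sample odds ratio as a ratio of within-arm odds, not the cross-product.
oracle_odds_ratio <- function(a, b, c, d) (a / b) / (c / d)

# Upper-tail hypergeometric probability by explicit binomial-coefficient
# summation over the support.
oracle_hypergeom_upper <- function(k, n, K, N) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Benjamini-Hochberg by the definitional double loop: for each p, the
# minimum over all p' >= p (by rank) of m * p' / rank(p'), capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ranked[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Random report tables for dedup fuzzing: cases with 1-3 versions, each
# version carrying 1-3 (drug, pt) rows.
fuzz_report_table <- function(n_cases, seed) {
  set.seed(seed)
  rows <- lapply(seq_len(n_cases), function(i) {
    n_ver <- sample(1:3, 1)
    dplyr::bind_rows(lapply(seq_len(n_ver), function(v) {
      n_rows <- sample(1:3, 1)
      make_records(
        report_id = sprintf("C%03d-%d", i, v),
        case_id = sprintf("C%03d", i),
        case_version = v,
        receipt_date = format(as.Date("2020-01-01") + sample(0:365, 1),
                              "%Y-%m-%d"),
        drug_name = sample(c("drugA", "drugB", "drugC"), n_rows,
                           replace = TRUE),
        drug_role = sample(c("PS", "SS", "C"), n_rows, replace = TRUE),
        pt_code = sample(sprintf("PT%03d", 1:5), n_rows, replace = TRUE))
    }))
  })
  dplyr::bind_rows(rows)
}
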