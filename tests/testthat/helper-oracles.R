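# Independent oracles and small fixture builders used across the suite.
# Oracles deliberately use different algorithms from the package code paths.

# Exact right-tail hypergeometric probability by rational enumeration.
# All binomial coefficients involved are bounded by choose(N, n) which for
# N <= 40 stays below 2^53, so choose() is exact integer arithmetic here and
# the single final division is correctly rounded.
oracle_hypergeom_right <- function(k, K, n, N) {
  if (k == 0) return(1)
  hi <- min(K, n)
  num <- sum(choose(K, k:hi) * choose(N - K, n - (k:hi)))
  num / choose(N, n)
}

# Brute-force shared-item network: for every unordered pair, intersect the
# two item sets directly. Returns a data frame from/to/weight with
# lexicographic endpoints, sorted, for edge-by-edge comparison.
oracle_shared_network <- function(sets) {
  mirnas <- sort(names(sets))
  rows <- list()
  for (i in seq_along(mirnas)) {
    for (j in seq_along(mirnas)) {
      if (i >= j) next
      shared <- intersect(sets[[mirnas[i]]], sets[[mirnas[j]]])
      if (length(shared)) {
        rows[[length(rows) + 1L]] <- data.frame(
          from = mirnas[i], to = mirnas[j], weight = length(shared),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(from = character(), to = character(),
                      weight = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$from, out$to), , drop = FALSE]
}

# Brute-force correlation network across the samples of a matrix.
oracle_correlation_network <- function(values, min_abs_r,
                                       method = "pearson") {
  mirnas <- sort(rownames(values))
  rows <- list()
  for (i in seq_along(mirnas)) {
    for (j in seq_along(mirnas)) {
      if (i >= j) next
      r <- cor(values[mirnas[i], ], values[mirnas[j], ], method = method)
      if (is.finite(r) && abs(r) >= min_abs_r && abs(r) > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          from = mirnas[i], to = mirnas[j], weight = abs(r), r = r,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(from = character(), to = character(),
                      weight = numeric(), r = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$from, out$to), , drop = FALSE]
}

# Fisher two-sided p by exhaustive enumeration over tables with the observed
# margins: sum the point hypergeometric probabilities of every table no more
# probable than the observed one.
oracle_fisher_two_sided <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  a_range <- max(0, c1 - (n - r1)):min(r1, c1)
  pr <- function(x) {
    choose(c1, x) * choose(n - c1, r1 - x) / choose(n, r1)
  }
  probs <- vapply(a_range, pr, numeric(1))
  obs <- pr(a)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Small hand-buildable expression matrix: values is a miRNA x sample matrix;
# classes/pairs derived from column names "<class>_<pair>".
toy_expression <- function(values) {
  cls <- sub("_.*$", "", colnames(values))
  pair <- sub("^.*_", "", colnames(values))
  expression_matrix(values, data.frame(
    sample_id = colnames(values), tissue_class = cls, pair_id = pair,
    stringsAsFactors = FALSE))
}

# Minimal enrichment-table row block for network tests.
toy_enrichment <- function(mirna_sets, p_adj = 0.01) {
  do.call(rbind, lapply(names(mirna_sets), function(m) {
    pws <- mirna_sets[[m]]
    if (!length(pws)) {
      return(data.frame(mirna = m, pathway = "PW_none", k = 0L, K = 5L,
                        n = 5L, N = 100L, p_raw = 1, p_adj = 1,
                        enriched = FALSE, stringsAsFactors = FALSE))
    }
    data.frame(mirna = m, pathway = pws, k = 4L, K = 5L, n = 5L, N = 100L,
               p_raw = p_adj, p_adj = p_adj, enriched = TRUE,
               stringsAsFactors = FALSE)
  }))
}
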