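#' Right-tail hypergeometric p-value
#'
#' Probability of observing at least `k` annotated genes when drawing `n`
#' genes from a universe of `N` that contains `K` annotated genes — the
#' right-sided hypergeometric test of pathway over-representation. Terms are
#' accumulated in log space (via `lchoose`) so large universes do not
#' overflow; on small instances the result matches exact rational enumeration
#' to better than ten significant digits.
#'
#' @param k Observed overlap (vectorised).
#' @param K Number of annotated genes in the universe (pathway size).
#' @param n Number of drawn genes (target-set size).
#' @param N Universe size.
#' @return `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`, vectorised over the
#'   inputs.
#' @examples
#' hypergeom_right_pvalue(5, 5, 5, 10) # 1/choose(10, 5)
#' @export
hypergeom_right_pvalue <- function(k, K, n, N) {
  lens <- c(length(k), length(K), length(n), length(N))
  len <- max(lens)
  if (any(lens != 1L & lens != len)) abort("arguments must be recyclable")
  k <- rep_len(as.numeric(k), len); K <- rep_len(as.numeric(K), len)
  n <- rep_len(as.numeric(n), len); N <- rep_len(as.numeric(N), len)
  if (anyNA(c(k, K, n, N)) || any(c(k, K, n, N) != trunc(c(k, K, n, N))) ||
      any(c(k, K, n, N) < 0)) {
    abort("k, K, n, N must be nonnegative integers")
  }
  if (any(K > N) || any(n > N) || any(k > pmin(K, n))) {
    abort("inconsistent counts: require k <= min(K, n) and max(K, n) <= N")
  }
  vapply(seq_len(len), function(i) {
    if (k[i] == 0) return(1)
    hi <- min(K[i], n[i])
    x <- k[i]:hi
    lt <- lchoose(K[i], x) + lchoose(N[i] - K[i], n[i] - x) -
      lchoose(N[i], n[i])
    mx <- max(lt)
    min(1, exp(mx + log(sum(exp(lt - mx)))))
  }, numeric(1))
}

#' Holm (Bonferroni step-down) p-value adjustment
#'
#' Sequentially rejective correction: with the `m` non-missing p-values
#' sorted ascending, the i-th adjusted value is
#' `min(1, max_{j <= i} (m - j + 1) * p_(j))`, returned in the original input
#' order. Uniformly more powerful than single-step Bonferroni while
#' controlling the family-wise error rate. `NA` entries are left `NA` and do
#' not count towards `m`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Adjusted p-values, same length and order as the input.
#' @examples
#' holm_adjust(c(0.01, 0.02, 0.03)) # 0.03 0.04 0.04
#' @export
holm_adjust <- function(p) {
  if (!is.numeric(p)) abort("p must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) abort("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  m <- sum(ok)
  if (m == 0L) return(out)
  pv <- p[ok]
  ord <- order(pv) # stable: ties keep input order
  stepped <- pmin(1, cummax((m - seq_len(m) + 1L) * pv[ord]))
  adj <- numeric(m)
  adj[ord] <- stepped
  out[ok] <- adj
  out
}

#' Cohen's kappa between two gene sets over a universe
#'
#' Chance-corrected agreement of the two binary membership indicator vectors:
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement
#' `p_o = (|A n B| + |A' n B'|) / N` and expected agreement `p_e` from the
#' marginal products. Identical indicators (including both sets empty or both
#' equal to the universe, where `p_e = 1`) give kappa 1. Used to group
#' redundant enriched pathway terms.
#'
#' @param set_a,set_b Character vectors of gene symbols, subsets of
#'   `universe`.
#' @param universe Non-empty character vector of the gene universe.
#' @return Kappa in `[-1, 1]`.
#' @examples
#' kappa_score(c("a", "b"), c("a", "b"), letters[1:6]) # 1
#' @export
kappa_score <- function(set_a, set_b, universe) {
  universe <- unique(as.character(universe))
  N <- length(universe)
  if (N == 0L) abort("universe must be non-empty")
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  if (length(setdiff(set_a, universe)) || length(setdiff(set_b, universe))) {
    abort("both sets must be subsets of the universe")
  }
  ina <- universe %in% set_a
  inb <- universe %in% set_b
  both <- sum(ina & inb)
  neither <- sum(!ina & !inb)
  p_o <- (both + neither) / N
  pa <- sum(ina) / N
  pb <- sum(inb) / N
  p_e <- pa * pb + (1 - pa) * (1 - pb)
  if (p_e == 1) return(1) # marginals degenerate => indicators identical
  (p_o - p_e) / (1 - p_e)
}

#' Per-miRNA target-set pathway enrichment
#'
#' Tests every (miRNA, pathway) combination with the right-sided
#' hypergeometric test: the target set (intersected with the universe) is the
#' draw, the pathway gene set the annotated class. P-values are Holm-adjusted
#' within each miRNA's family of pathway tests — enrichment is run per target
#' list, not over the global miRNA x pathway grid — and rows with adjusted
#' p at or below `p_threshold` are flagged enriched.
#'
#' @param target_map Named list: miRNA -> character vector of target genes.
#' @param pathway_db Named list: pathway id -> character vector of genes.
#' @param universe Gene universe; defaults to the union of all pathway genes.
#' @param p_threshold Adjusted-p cutoff for the `enriched` flag.
#' @return A data frame of class `enrichment_table` with one row per tested
#'   (miRNA, pathway): columns `mirna`, `pathway`, `k` (overlap), `K`
#'   (pathway size in universe), `n` (targets in universe), `N` (universe
#'   size), `p_raw`, `p_adj`, `enriched`. miRNAs whose intersected target set
#'   is empty are skipped with a warning.
#' @export
enrich_mirna_targets <- function(target_map, pathway_db, universe = NULL,
                                 p_threshold = 0.05) {
  if (!is.list(pathway_db) || length(pathway_db) == 0L ||
      is.null(names(pathway_db))) {
    abort("pathway_db must be a non-empty named list")
  }
  if (!is.list(target_map) || is.null(names(target_map))) {
    abort("target_map must be a named list")
  }
  if (!is_prob(p_threshold)) abort("p_threshold must be a probability")
  if (is.null(universe)) {
    universe <- sort(unique(unlist(pathway_db, use.names = FALSE)))
  }
  universe <- unique(as.character(universe))
  N <- length(universe)
  if (N == 0L) abort("gene universe is empty")
  pw_sets <- lapply(pathway_db, function(g) intersect(unique(g), universe))
  pw_ids <- names(pathway_db)

  rows <- lapply(names(target_map), function(m) {
    targets <- intersect(unique(as.character(target_map[[m]])), universe)
    n <- length(targets)
    if (n == 0L) {
      warning(sprintf(
        "miRNA '%s' has no targets inside the universe; skipped", m),
        call. = FALSE)
      return(NULL)
    }
    k <- vapply(pw_sets, function(g) length(intersect(g, targets)),
                integer(1))
    K <- lengths(pw_sets)
    p_raw <- hypergeom_right_pvalue(k, K, n, N)
    data.frame(mirna = m, pathway = pw_ids, k = as.integer(k),
               K = as.integer(K), n = n, N = N, p_raw = p_raw,
               p_adj = holm_adjust(p_raw), row.names = NULL,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(mirna = character(), pathway = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p_raw = numeric(), p_adj = numeric(),
                      stringsAsFactors = FALSE)
  }
  out$enriched <- out$p_adj <= p_threshold
  attr(out, "p_threshold") <- p_threshold
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Group one miRNA's enriched pathways by kappa similarity
#'
#' Builds the graph whose vertices are the enriched pathways of a single
#' miRNA and whose edges join pathway pairs with gene-membership kappa at or
#' above `kappa_threshold`, then takes connected components (single-linkage
#' grouping). Each group's representative is its lowest-adjusted-p member,
#' ties broken by lexicographic pathway id.
#'
#' @param enrichment An [enrich_mirna_targets()] table restricted to (or
#'   containing) a single miRNA; only rows with `enriched == TRUE` are
#'   grouped.
#' @param pathway_db Named list of pathway gene sets.
#' @param universe Gene universe used for the kappa computation; defaults to
#'   the union of all `pathway_db` genes.
#' @param kappa_threshold Minimum kappa for two pathways to be linked.
#' @return A list of term groups, ordered by representative `p_adj` (ties by
#'   representative id). Each element has `members` (pathway ids), `kappa`
#'   (pairwise kappa matrix among members) and `representative`.
#' @export
group_terms <- function(enrichment, pathway_db, universe = NULL,
                        kappa_threshold = 0.3) {
  stopifnot(is.data.frame(enrichment))
  if (length(unique(enrichment$mirna)) > 1L) {
    abort("group_terms expects enrichment rows of a single miRNA")
  }
  rows <- enrichment[isTRUE_v(enrichment$enriched), , drop = FALSE]
  if (nrow(rows) == 0L) abort("no enriched rows to group")
  if (is.null(universe)) {
    universe <- sort(unique(unlist(pathway_db, use.names = FALSE)))
  }
  ids <- sort(unique(rows$pathway))
  if (length(setdiff(ids, names(pathway_db)))) {
    abort("enriched pathways missing from pathway_db")
  }
  kap <- matrix(1, length(ids), length(ids), dimnames = list(ids, ids))
  if (length(ids) > 1L) {
    cmb <- utils::combn(seq_along(ids), 2L)
    for (j in seq_len(ncol(cmb))) {
      i1 <- cmb[1L, j]; i2 <- cmb[2L, j]
      kv <- kappa_score(pathway_db[[ids[i1]]], pathway_db[[ids[i2]]],
                        universe)
      kap[i1, i2] <- kv
      kap[i2, i1] <- kv
    }
  }
  adj <- kap >= kappa_threshold
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  p_adj <- rows$p_adj[match(ids, rows$pathway)]
  groups <- lapply(split(ids, comp), function(members) {
    pm <- p_adj[match(members, ids)]
    ord <- order(pm, members)
    list(members = members,
         kappa = kap[members, members, drop = FALSE],
         representative = members[ord[1L]],
         representative_p_adj = pm[ord[1L]])
  })
  rep_p <- vapply(groups, `[[`, numeric(1), "representative_p_adj")
  rep_id <- vapply(groups, `[[`, character(1), "representative")
  unname(groups[order(rep_p, rep_id)])
}

# all-TRUE test robust to NA logical columns
isTRUE_v <- function(x) !is.na(x) & x
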