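#' Construct a validated miRNA synergy network
#'
#' Internal constructor shared by the three network builders. Edges are
#' undirected; endpoints are canonicalised so `from < to` lexicographically
#' and rows are sorted by (`from`, `to`), making every build — and every
#' serialisation — deterministic. Hub scores are the weighted degrees.
#'
#' @param mirnas Character vector of node labels (isolates retained).
#' @param edges Data frame with columns `from`, `to`, `weight` (> 0),
#'   `evidence` (character) and optionally extra columns (e.g. `r`).
#' @param kind Network flavour, recorded as an attribute.
#' @return Object of class `synergy_network`: list with `nodes` (data frame
#'   `mirna`, `hub_score`) and `edges`.
#' @keywords internal
new_synergy_network <- function(mirnas, edges, kind = "generic") {
  mirnas <- as.character(mirnas)
  if (anyDuplicated(mirnas)) abort("duplicated node labels")
  base_cols <- c("from", "to", "weight", "evidence")
  if (nrow(edges)) {
    if (length(setdiff(base_cols, names(edges)))) {
      abort("edges need columns from, to, weight, evidence")
    }
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    if (any(edges$from == edges$to)) abort("self-loops are not allowed")
    if (any(!c(edges$from, edges$to) %in% mirnas)) {
      abort("edge endpoint not among nodes")
    }
    if (any(!is.finite(edges$weight)) || any(edges$weight <= 0)) {
      abort("edge weights must be positive")
    }
    flip <- edges$from > edges$to
    tmp <- edges$from[flip]
    edges$from[flip] <- edges$to[flip]
    edges$to[flip] <- tmp
    if (anyDuplicated(edges[, c("from", "to")])) {
      abort("duplicate edges between the same endpoints")
    }
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), evidence = character(),
                        stringsAsFactors = FALSE)
  }
  hub <- setNames(numeric(length(mirnas)), mirnas)
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      hub[edges$from[i]] <- hub[edges$from[i]] + edges$weight[i]
      hub[edges$to[i]] <- hub[edges$to[i]] + edges$weight[i]
    }
  }
  nodes <- data.frame(mirna = mirnas, hub_score = unname(hub),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$mirna), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges),
            class = "synergy_network", kind = kind)
}

#' @export
print.synergy_network <- function(x, ...) {
  cat(sprintf("synergy_network (%s): %d nodes, %d edges\n",
              attr(x, "kind"), nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Pathway-co-regulation synergy network
#'
#' Two miRNAs are synergistic when they co-regulate at least one pathway:
#' an edge joins every miRNA pair sharing one or more *enriched* pathways,
#' with weight equal to the number of shared enriched pathways and the shared
#' pathway ids as evidence. miRNAs present in the enrichment table but
#' sharing nothing are kept as isolates with hub score 0.
#'
#' @param enrichment An [enrich_mirna_targets()] table covering at least two
#'   miRNAs.
#' @return A `synergy_network`.
#' @export
pathway_synergy_network <- function(enrichment) {
  stopifnot(is.data.frame(enrichment))
  mirnas <- sort(unique(enrichment$mirna))
  if (length(mirnas) < 2L) {
    abort("enrichment must cover at least two miRNAs")
  }
  enr <- enrichment[isTRUE_v(enrichment$enriched), , drop = FALSE]
  sets <- split(enr$pathway, enr$mirna)
  shared_set_network(mirnas, sets, kind = "pathway")
}

#' Shared-target synergy network
#'
#' The alternative, annotation-only reading of synergy: an edge joins two
#' miRNAs that share at least one verified target gene, weighted by the
#' number of shared targets. Provided alongside
#' [pathway_synergy_network()] for users who want raw target overlap rather
#' than co-enriched pathways.
#'
#' @param target_map Named list: miRNA -> character vector of target genes.
#' @return A `synergy_network`.
#' @export
target_synergy_network <- function(target_map) {
  if (!is.list(target_map) || is.null(names(target_map)) ||
      length(target_map) < 2L) {
    abort("target_map must be a named list of at least two miRNAs")
  }
  mirnas <- sort(names(target_map))
  sets <- lapply(target_map, function(g) unique(as.character(g)))
  shared_set_network(mirnas, sets, kind = "target")
}

#' Shared-transcription-factor synergy network
#'
#' An edge joins two miRNAs regulated by at least one common transcription
#' factor; weight is the number of shared TFs, evidence their symbols.
#'
#' @param tf_map Named list: TF symbol -> character vector of regulated
#'   miRNAs.
#' @param mirnas Node labels to include (isolates retained).
#' @return A `synergy_network`.
#' @export
tf_synergy_network <- function(tf_map, mirnas) {
  if (!is.list(tf_map) || length(tf_map) == 0L || is.null(names(tf_map))) {
    abort("tf_map must be a non-empty named list")
  }
  mirnas <- sort(unique(as.character(mirnas)))
  if (length(mirnas) < 2L) abort("need at least two miRNAs")
  # invert: miRNA -> regulating TFs (restricted to requested nodes)
  sets <- setNames(vector("list", length(mirnas)), mirnas)
  for (tf in names(tf_map)) {
    for (m in intersect(as.character(tf_map[[tf]]), mirnas)) {
      sets[[m]] <- c(sets[[m]], tf)
    }
  }
  shared_set_network(mirnas, sets, kind = "tf")
}

# Common core of the pathway/target/TF networks: edge iff the per-miRNA sets
# intersect; weight = intersection size; evidence = sorted shared items.
shared_set_network <- function(mirnas, sets, kind) {
  sets <- lapply(mirnas, function(m) {
    s <- sets[[m]]
    if (is.null(s)) character(0) else sort(unique(as.character(s)))
  })
  names(sets) <- mirnas
  from <- character(0); to <- character(0)
  weight <- numeric(0); evidence <- character(0)
  if (length(mirnas) > 1L) {
    cmb <- utils::combn(seq_along(mirnas), 2L)
    for (j in seq_len(ncol(cmb))) {
      shared <- intersect(sets[[cmb[1L, j]]], sets[[cmb[2L, j]]])
      if (length(shared)) {
        from <- c(from, mirnas[cmb[1L, j]])
        to <- c(to, mirnas[cmb[2L, j]])
        weight <- c(weight, length(shared))
        evidence <- c(evidence, paste(shared, collapse = ";"))
      }
    }
  }
  new_synergy_network(mirnas,
                      data.frame(from = from, to = to, weight = weight,
                                 evidence = evidence,
                                 stringsAsFactors = FALSE),
                      kind = kind)
}

#' Expression-correlation synergy network
#'
#' Within one tissue class, correlates every miRNA pair across samples and
#' joins pairs whose |r| reaches `min_abs_r`. Edge weight is |r|; the signed
#' coefficient is kept in the `r` column and echoed in the evidence string,
#' so inverse relationships (such as miR-155 against miR-143 in normal
#' mucosa) stay visible.
#'
#' @param expr An [expression_matrix()].
#' @param tissue_class Class whose samples are correlated.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param min_abs_r Absolute-correlation threshold for an edge.
#' @return A `synergy_network`; zero-variance miRNAs are dropped with a
#'   warning.
#' @export
correlation_network <- function(expr, tissue_class,
                                method = c("pearson", "spearman"),
                                min_abs_r = 0.7) {
  stopifnot(inherits(expr, "expression_matrix"))
  method <- match.arg(method)
  if (!is.numeric(min_abs_r) || min_abs_r < 0 || min_abs_r > 1) {
    abort("min_abs_r must lie in [0, 1]")
  }
  sub <- subset_class(expr, tissue_class)
  if (ncol(sub$values) < 3L) {
    abort(sprintf("need at least 3 samples of class '%s' (found %d)",
                  tissue_class, ncol(sub$values)))
  }
  v <- apply(sub$values, 1L, sd)
  if (any(v == 0)) {
    warning(sprintf("%d zero-variance miRNA(s) excluded from correlation",
                    sum(v == 0)), call. = FALSE)
  }
  vals <- sub$values[v > 0, , drop = FALSE]
  mirnas <- sort(rownames(vals))
  cm <- cor(t(vals), method = method)
  from <- character(0); to <- character(0)
  weight <- numeric(0); evidence <- character(0); rs <- numeric(0)
  if (length(mirnas) > 1L) {
    cmb <- utils::combn(seq_along(mirnas), 2L)
    for (j in seq_len(ncol(cmb))) {
      m1 <- mirnas[cmb[1L, j]]; m2 <- mirnas[cmb[2L, j]]
      r <- cm[m1, m2]
      if (is.finite(r) && abs(r) >= min_abs_r && abs(r) > 0) {
        from <- c(from, m1); to <- c(to, m2)
        weight <- c(weight, abs(r)); rs <- c(rs, r)
        evidence <- c(evidence, sprintf("r=%+.6f", r))
      }
    }
  }
  edges <- data.frame(from = from, to = to, weight = weight,
                      evidence = evidence, r = rs,
                      stringsAsFactors = FALSE)
  new_synergy_network(mirnas, edges, kind = paste0("correlation_", method))
}

#' Rank miRNAs by hub score
#'
#' Hub score is the weighted degree — the sum of incident edge weights — the
#' quantity a node's drawn size reflects in synergy-network figures; the top
#' entry is the network's principal hub.
#'
#' @param network A `synergy_network`.
#' @return Data frame `mirna`, `hub_score`, sorted by descending score, ties
#'   broken lexicographically.
#' @export
hub_ranking <- function(network) {
  stopifnot(inherits(network, "synergy_network"))
  nodes <- network$nodes
  nodes <- nodes[order(-nodes$hub_score, nodes$mirna), , drop = FALSE]
  rownames(nodes) <- NULL
  nodes
}
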