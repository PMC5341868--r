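#' Write an expression matrix and its metadata to tab-separated files
#'
#' @param expr An [expression_matrix()].
#' @param path Destination of the matrix: first column `mirna`, then one
#'   column per sample.
#' @param metadata_path Destination of the metadata table (`sample_id`,
#'   `tissue_class`, `pair_id`).
#' @return Invisibly, `path`.
#' @export
write_expression <- function(expr, path, metadata_path) {
  stopifnot(inherits(expr, "expression_matrix"))
  # %.17g round-trips doubles exactly through text
  chr <- matrix(sprintf("%.17g", expr$values), nrow(expr$values),
                dimnames = dimnames(expr$values))
  df <- data.frame(mirna = rownames(expr$values), chr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(expr$metadata, metadata_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix with sample metadata
#'
#' Reads a tab-separated numeric matrix (first column miRNA id, header of
#' sample ids) together with its metadata table and validates them jointly:
#' duplicated miRNA ids, samples without metadata, non-numeric cells and
#' header-only files are all rejected rather than repaired.
#'
#' @param path Expression matrix file.
#' @param metadata_path Metadata file with columns `sample_id`,
#'   `tissue_class`, `pair_id`.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, metadata_path) {
  raw <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (nrow(raw) == 0L) {
    abort(sprintf("'%s' contains a header but no miRNA rows", path),
          "crcmirnet_structure_error")
  }
  if (ncol(raw) < 2L) {
    abort(sprintf("'%s' has no sample columns", path),
          "crcmirnet_structure_error")
  }
  ids <- raw[[1L]]
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicated miRNA id(s) in '%s': %s", path,
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          "crcmirnet_structure_error")
  }
  num <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw)))
  )
  num <- matrix(num, nrow = nrow(raw),
                dimnames = list(ids, names(raw)[-1L]))
  bad <- which(is.na(num) & !is.na(as.matrix(raw[-1L])) &
                 as.matrix(raw[-1L]) != "NA", arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf(
      "non-numeric cell in '%s' at row %d (miRNA '%s'), sample column '%s'",
      path, bad[1L, 1L], ids[bad[1L, 1L]], colnames(num)[bad[1L, 2L]]),
      "crcmirnet_parse_error")
  }
  metadata <- read.delim(metadata_path, stringsAsFactors = FALSE,
                         colClasses = "character")
  expression_matrix(num, metadata)
}

#' Read gene sets in GMT format
#'
#' Standard GMT dialect: one pathway per line,
#' `id <TAB> description <TAB> gene <TAB> gene ...`. Duplicate genes within a
#' line are collapsed with a warning; duplicate pathway ids and lines with
#' fewer than three fields are errors.
#'
#' @param path GMT file.
#' @return Named list of character gene sets, with the per-pathway
#'   descriptions in `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) abort("empty GMT file", "crcmirnet_parse_error")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    abort(sprintf("GMT line %d has fewer than 3 fields", short[1L]),
          "crcmirnet_parse_error")
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicated pathway id(s) in GMT: %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          "crcmirnet_structure_error")
  }
  desc <- vapply(fields, `[[`, character(1), 2L)
  sets <- lapply(fields, function(f) {
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      warning(sprintf("duplicate gene(s) within GMT set '%s' collapsed",
                      f[[1L]]), call. = FALSE)
    }
    sort(unique(genes))
  })
  names(sets) <- ids
  attr(sets, "description") <- setNames(desc, ids)
  sets
}

#' Write gene sets in GMT format
#'
#' @param pathway_db Named list of gene sets.
#' @param path Destination file.
#' @param description Optional named character vector of descriptions;
#'   defaults to the ids.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(pathway_db, path, description = NULL) {
  if (!is.list(pathway_db) || is.null(names(pathway_db))) {
    abort("pathway_db must be a named list")
  }
  if (is.null(description)) {
    description <- attr(pathway_db, "description")
  }
  if (is.null(description)) {
    description <- setNames(names(pathway_db), names(pathway_db))
  }
  lines <- vapply(names(pathway_db), function(id) {
    paste(c(id, description[[id]], sort(unique(pathway_db[[id]]))),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a miRNA-to-target annotation table
#'
#' Two tab-separated columns, `mirna` and `target_gene`, one interaction per
#' row (the layout of curated miRNA-target distribution files).
#'
#' @param path Annotation file.
#' @return Named list: miRNA -> sorted unique target genes.
#' @export
read_target_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("mirna", "target_gene") %in% names(df))) {
    abort("target table needs columns 'mirna' and 'target_gene'",
          "crcmirnet_structure_error")
  }
  lapply(split(df$target_gene, df$mirna), function(g) sort(unique(g)))
}

#' @rdname read_target_map
#' @param target_map Named list: miRNA -> target genes.
#' @export
write_target_map <- function(target_map, path) {
  df <- data.frame(
    mirna = rep(names(target_map), lengths(target_map)),
    target_gene = unlist(target_map, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TF-to-miRNA regulation table
#'
#' Two tab-separated columns, `tf` and `mirna`, one regulation per row (the
#' layout of TF-miRNA regulation databases).
#'
#' @param path Regulation file.
#' @return Named list: TF -> sorted unique regulated miRNAs.
#' @export
read_tf_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("tf", "mirna") %in% names(df))) {
    abort("TF table needs columns 'tf' and 'mirna'",
          "crcmirnet_structure_error")
  }
  lapply(split(df$mirna, df$tf), function(m) sort(unique(m)))
}

#' @rdname read_tf_map
#' @param tf_map Named list: TF -> regulated miRNAs.
#' @export
write_tf_map <- function(tf_map, path) {
  df <- data.frame(
    tf = rep(names(tf_map), lengths(tf_map)),
    mirna = unlist(tf_map, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a synergy network
#'
#' GraphML output carries the `hub_score` node attribute and the `weight` and
#' `evidence` edge attributes (plus `r` for correlation networks); the edge
#' list is three tab-separated columns `mirna_a`, `mirna_b`, `weight` with
#' lexicographically ordered endpoints and rows, so repeated exports diff
#' cleanly.
#'
#' @param network A `synergy_network`.
#' @param path Destination file.
#' @param format `"graphml"` or `"edgelist"`.
#' @return Invisibly, `path`.
#' @export
write_network <- function(network, path, format = c("graphml", "edgelist")) {
  stopifnot(inherits(network, "synergy_network"))
  format <- match.arg(format)
  if (format == "edgelist") {
    df <- network$edges[, c("from", "to", "weight")]
    names(df) <- c("mirna_a", "mirna_b", "weight")
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  g <- igraph::graph_from_data_frame(
    network$edges, directed = FALSE,
    vertices = data.frame(name = network$nodes$mirna,
                          hub_score = network$nodes$hub_score,
                          stringsAsFactors = FALSE)
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a synergy network written by [write_network()]
#'
#' @param path Source file.
#' @param format `"graphml"` or `"edgelist"` (edge lists carry no evidence;
#'   it is restored as an empty string).
#' @return A `synergy_network`.
#' @export
read_network <- function(path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    df <- read.delim(path, stringsAsFactors = FALSE)
    if (nrow(df) == 0L) {
      return(new_synergy_network(character(0), df[0, ]))
    }
    edges <- data.frame(from = df$mirna_a, to = df$mirna_b,
                        weight = df$weight, evidence = "",
                        stringsAsFactors = FALSE)
    return(new_synergy_network(sort(unique(c(df$mirna_a, df$mirna_b))),
                               edges))
  }
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- igraph::vertex_attr(g, "name")
  el <- igraph::as_edgelist(g)
  edges <- data.frame(
    from = el[, 1L], to = el[, 2L],
    weight = igraph::edge_attr(g, "weight"),
    evidence = igraph::edge_attr(g, "evidence"),
    stringsAsFactors = FALSE
  )
  if (!is.null(igraph::edge_attr(g, "r"))) {
    edges$r <- igraph::edge_attr(g, "r")
  }
  if (igraph::ecount(g) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), evidence = character(),
                        stringsAsFactors = FALSE)
  }
  new_synergy_network(nodes, edges)
}

#' Write the generator configuration as a YAML sidecar
#'
#' Records the full simulation configuration (including the seed) next to
#' generated outputs so any run can be reproduced from its sidecar alone.
#'
#' @param config A [simulation_config()] or plain named list.
#' @param path Destination YAML file.
#' @return Invisibly, `path`.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @return For `read_config_yaml`, the named list stored in the file.
#' @export
read_config_yaml <- function(path) {
  out <- yaml::read_yaml(path)
  if (is.null(out)) list() else out
}

#' Write a differential table or enrichment table as tab-separated text
#'
#' @param x A data frame (e.g. `diff_table` or `enrichment_table`).
#' @param path Destination file.
#' @return Invisibly, `path`.
#' @export
write_table_tsv <- function(x, path) {
  stopifnot(is.data.frame(x))
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
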