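#' Construct an expression matrix with paired sample metadata
#'
#' The central container of the pipeline: a numeric matrix of log2 miRNA
#' abundances (miRNAs in rows, samples in columns) bound to a metadata table
#' that records, for every sample, its tissue class and the patient pair it
#' belongs to. All downstream stages (differential calling, correlation
#' networks) consume this object.
#'
#' @param values Numeric matrix, miRNAs x samples, with unique non-empty
#'   rownames (miRNA ids) and colnames (sample ids), on log2 scale.
#' @param metadata Data frame with columns `sample_id`, `tissue_class`
#'   (one of [tissue_classes()]) and `pair_id`. One row per column of
#'   `values`; each `pair_id` may appear at most once per tissue class.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` and `metadata` (metadata reordered to match the columns).
#' @examples
#' vals <- matrix(rnorm(6), 2, 3,
#'   dimnames = list(c("miR-1", "miR-2"), c("s1", "s2", "s3")))
#' md <- data.frame(sample_id = c("s1", "s2", "s3"),
#'   tissue_class = c("normal", "adenoma", "carcinoma"),
#'   pair_id = "p01")
#' expression_matrix(vals, md)
#' @export
expression_matrix <- function(values, metadata) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix", "crcmirnet_structure_error")
  }
  if (nrow(values) == 0L || ncol(values) == 0L) {
    abort("expression matrix must have at least one miRNA and one sample",
          "crcmirnet_structure_error")
  }
  rn <- rownames(values)
  cn <- colnames(values)
  if (is.null(rn) || anyNA(rn) || any(rn == "")) {
    abort("expression matrix needs non-empty miRNA rownames",
          "crcmirnet_structure_error")
  }
  if (anyDuplicated(rn)) {
    abort(sprintf("duplicated miRNA id(s): %s",
                  paste(unique(rn[duplicated(rn)]), collapse = ", ")),
          "crcmirnet_structure_error")
  }
  if (is.null(cn) || anyDuplicated(cn)) {
    abort("expression matrix needs unique sample colnames",
          "crcmirnet_structure_error")
  }
  metadata <- validate_metadata(metadata)
  if (!setequal(cn, metadata$sample_id)) {
    missing_md <- setdiff(cn, metadata$sample_id)
    extra_md <- setdiff(metadata$sample_id, cn)
    abort(sprintf(
      "sample ids of matrix and metadata disagree (missing metadata: %s; unmatched metadata: %s)",
      paste(missing_md, collapse = ", "), paste(extra_md, collapse = ", ")),
      "crcmirnet_structure_error")
  }
  metadata <- metadata[match(cn, metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(values = values, metadata = metadata),
            class = "expression_matrix")
}

# Validate a sample-metadata table: required columns, known tissue classes,
# unique sample ids, and at most one sample per (pair, class).
validate_metadata <- function(metadata) {
  if (!is.data.frame(metadata)) {
    abort("metadata must be a data frame", "crcmirnet_structure_error")
  }
  needed <- c("sample_id", "tissue_class", "pair_id")
  miss <- setdiff(needed, names(metadata))
  if (length(miss)) {
    abort(sprintf("metadata lacks column(s): %s", paste(miss, collapse = ", ")),
          "crcmirnet_structure_error")
  }
  metadata$sample_id <- as.character(metadata$sample_id)
  metadata$tissue_class <- as.character(metadata$tissue_class)
  metadata$pair_id <- as.character(metadata$pair_id)
  if (anyDuplicated(metadata$sample_id)) {
    abort("metadata sample ids must be unique", "crcmirnet_structure_error")
  }
  bad <- setdiff(unique(metadata$tissue_class), tissue_classes())
  if (length(bad)) {
    abort(sprintf("unknown tissue class(es): %s", paste(bad, collapse = ", ")),
          "crcmirnet_structure_error")
  }
  key <- paste(metadata$pair_id, metadata$tissue_class)
  if (anyDuplicated(key)) {
    abort(sprintf("pair/class combination duplicated: %s",
                  paste(unique(key[duplicated(key)]), collapse = ", ")),
          "crcmirnet_structure_error")
  }
  metadata[, needed]
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d miRNAs x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$metadata$tissue_class)
  cat("samples per class:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Subset an expression matrix to one tissue class
#'
#' @param expr An [expression_matrix()].
#' @param tissue_class One of [tissue_classes()].
#' @return An `expression_matrix` restricted to that class's samples.
#' @export
subset_class <- function(expr, tissue_class) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (!is_string(tissue_class) || !tissue_class %in% tissue_classes()) {
    abort("unknown tissue class", "crcmirnet_structure_error")
  }
  keep <- expr$metadata$tissue_class == tissue_class
  if (!any(keep)) {
    abort(sprintf("no samples of class '%s'", tissue_class),
          "crcmirnet_structure_error")
  }
  expression_matrix(expr$values[, keep, drop = FALSE],
                    expr$metadata[keep, , drop = FALSE])
}
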