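#' Paired differential miRNA calling
#'
#' For every miRNA, computes the mean paired log2 difference between two
#' tissue classes (class_b minus class_a, pairs matched by `pair_id`) and a
#' two-sided paired t-test p-value. A miRNA is called `up` when the
#' (optionally adjusted) p-value is below `alpha` and its log2 fold change is
#' at least `fc_threshold`; `down` symmetrically; otherwise `ns`.
#'
#' Degenerate cases are handled explicitly rather than propagated as `NaN`:
#' a miRNA with zero within-pair variance gets p = 0 if its mean difference is
#' non-zero (the paired differences are identical and non-null) and p = 1
#' otherwise, flagged `degenerate_variance`; a miRNA with any missing paired
#' value is called `ns` and flagged `incomplete_pairs`.
#'
#' @param expr An [expression_matrix()].
#' @param class_a Reference tissue class (e.g. `"normal"`).
#' @param class_b Comparison tissue class (e.g. `"carcinoma"`); positive
#'   log2fc means higher in `class_b`.
#' @param fc_threshold Minimum |log2 fold change| required for a call.
#' @param alpha Significance level applied to the (adjusted) p-value.
#' @param adjust Multiple-testing adjustment across miRNAs: `"none"` (raw
#'   p < alpha, the convention of array figure legends reading
#'   "t-test; P < 0.05"), `"holm"`, or `"bh"`.
#' @return A data frame of class `diff_table` with columns `mirna`, `log2fc`,
#'   `p_value`, `p_adj`, `call` and `flags`, one row per miRNA, in the row
#'   order of `expr`. The adjustment method is recorded in
#'   `attr(, "adjust")`.
#' @examples
#' expr <- simulate_expression(simulation_config(n_mirnas = 60, seed = 3))
#' head(differential_mirnas(expr, "normal", "carcinoma"))
#' @export
differential_mirnas <- function(expr, class_a, class_b, fc_threshold = 1.0,
                                alpha = 0.05,
                                adjust = c("none", "holm", "bh")) {
  stopifnot(inherits(expr, "expression_matrix"))
  adjust <- match.arg(adjust)
  if (!is.numeric(fc_threshold) || fc_threshold < 0) {
    abort("fc_threshold must be >= 0")
  }
  if (!is_prob(alpha)) abort("alpha must be a probability")
  md <- expr$metadata
  for (cl in c(class_a, class_b)) {
    if (!cl %in% tissue_classes()) {
      abort(sprintf("unknown tissue class '%s'", cl))
    }
  }
  a_md <- md[md$tissue_class == class_a, , drop = FALSE]
  b_md <- md[md$tissue_class == class_b, , drop = FALSE]
  pairs <- intersect(a_md$pair_id, b_md$pair_id)
  if (length(pairs) < 2L) {
    abort(sprintf(
      "need at least 2 complete pairs between '%s' and '%s' (found %d)",
      class_a, class_b, length(pairs)))
  }
  a_cols <- a_md$sample_id[match(pairs, a_md$pair_id)]
  b_cols <- b_md$sample_id[match(pairs, b_md$pair_id)]
  d <- expr$values[, b_cols, drop = FALSE] - expr$values[, a_cols, drop = FALSE]

  k <- length(pairs)
  complete <- rowSums(is.na(d)) == 0L
  log2fc <- rowMeans(d, na.rm = TRUE)
  sds <- apply(d, 1L, sd, na.rm = TRUE)
  tstat <- log2fc / (sds / sqrt(k))
  p <- 2 * pt(-abs(tstat), df = k - 1L)

  degen <- complete & sds == 0
  p[degen] <- ifelse(abs(log2fc[degen]) > 0, 0, 1)
  p[!complete] <- NA_real_
  log2fc[!complete & !is.finite(log2fc)] <- NA_real_

  p_adj <- switch(adjust,
    none = p,
    holm = holm_adjust(p),
    bh = p.adjust(p, method = "BH")
  )
  signif_call <- !is.na(p_adj) & p_adj < alpha
  call <- rep("ns", nrow(d))
  call[signif_call & log2fc >= fc_threshold] <- "up"
  call[signif_call & log2fc <= -fc_threshold] <- "down"
  call[!complete] <- "ns"

  flags <- rep("", nrow(d))
  flags[degen] <- "degenerate_variance"
  flags[!complete] <- "incomplete_pairs"

  out <- data.frame(
    mirna = rownames(expr$values), log2fc = log2fc, p_value = p,
    p_adj = p_adj, call = call, flags = flags,
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "adjust") <- adjust
  attr(out, "comparison") <- c(class_a = class_a, class_b = class_b)
  class(out) <- c("diff_table", "data.frame")
  out
}

#' Relative expression by the comparative Ct method
#'
#' Computes `2^-ddCt` where
#' `ddCt = (Ct_target - Ct_reference)_sample - (Ct_target - Ct_reference)_calibrator`.
#' Any input cycle threshold at or above `ct_cutoff` (default 30) means the
#' amplification was too low to quantify; the function then returns `NA` with
#' attribute `unquantifiable = TRUE` rather than an arithmetic result.
#'
#' @param ct_target,ct_reference Ct values for the target and reference
#'   (housekeeping) assay in the test sample.
#' @param calibrator_ct_target,calibrator_ct_reference The same for the
#'   calibrator (control) sample.
#' @param ct_cutoff Censoring threshold; Ct at or above it is unquantifiable.
#' @return The fold change `2^-ddCt`, or `NA` (with attribute
#'   `unquantifiable`) when any input is censored.
#' @examples
#' relative_expression_ddct(25, 20, 24, 19) # ddCt = 0 -> 1
#' relative_expression_ddct(26, 20, 24, 19) # ddCt = 1 -> 0.5
#' @export
relative_expression_ddct <- function(ct_target, ct_reference,
                                     calibrator_ct_target,
                                     calibrator_ct_reference,
                                     ct_cutoff = 30) {
  cts <- c(ct_target, ct_reference, calibrator_ct_target,
           calibrator_ct_reference)
  if (length(cts) != 4L || anyNA(cts) || !is.numeric(cts)) {
    abort("all four Ct values must be supplied")
  }
  if (any(cts < 0)) abort("Ct values must be nonnegative")
  if (any(cts >= ct_cutoff)) {
    return(structure(NA_real_, unquantifiable = TRUE))
  }
  ddct <- (ct_target - ct_reference) -
    (calibrator_ct_target - calibrator_ct_reference)
  2^(-ddct)
}

#' Dual-luciferase reporter normalization
#'
#' Firefly activity is normalized to the co-transfected Renilla control and
#' expressed relative to the scramble-control well:
#' `(firefly/renilla) / (control_firefly/control_renilla)`.
#'
#' @param firefly,renilla Readings from the test well.
#' @param control_firefly,control_renilla Readings from the control well.
#' @return Relative reporter activity (nonnegative).
#' @export
normalize_reporter <- function(firefly, renilla, control_firefly,
                               control_renilla) {
  vals <- c(firefly, renilla, control_firefly, control_renilla)
  if (anyNA(vals) || !is.numeric(vals) || any(vals < 0)) {
    abort("reporter readings must be nonnegative numbers")
  }
  if (renilla == 0 || control_renilla == 0) {
    abort("Renilla readings must be strictly positive")
  }
  (firefly / renilla) / (control_firefly / control_renilla)
}

#' Relative cell viability from absorbance
#'
#' @param absorbance Test-well absorbance (e.g. MTT at 490 nm).
#' @param control_absorbance Control-well absorbance; must be positive.
#' @return `absorbance / control_absorbance`.
#' @export
relative_viability <- function(absorbance, control_absorbance) {
  if (!is.numeric(absorbance) || absorbance < 0) {
    abort("absorbance must be nonnegative")
  }
  if (!is.numeric(control_absorbance) || control_absorbance <= 0) {
    abort("control absorbance must be positive")
  }
  absorbance / control_absorbance
}

#' Xenograft tumor volume
#'
#' The standard caliper formula `width^2 * length / 2`, in cubic millimetres
#' when inputs are in millimetres.
#'
#' @param width,length Caliper measurements, nonnegative, in mm.
#' @return Volume in mm^3.
#' @examples
#' tumor_volume(5, 10) # 125
#' @export
tumor_volume <- function(width, length) {
  if (!is.numeric(width) || !is.numeric(length) || width < 0 || length < 0) {
    abort("width and length must be nonnegative")
  }
  width^2 * length / 2
}
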