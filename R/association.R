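#' A 2x2 marker-positivity contingency table
#'
#' Cell layout follows the joint-positivity tables of immunohistochemistry
#' studies: rows are marker status, columns exposure status, so
#' `a` = exposure+/marker+, `b` = exposure-/marker+, `c` = exposure+/marker-,
#' `d` = exposure-/marker-.
#'
#' @param a,b,c,d Nonnegative integer cell counts; their sum must be
#'   positive.
#' @return Object of class `contingency_2x2`.
#' @examples
#' contingency_2x2(28, 21, 9, 20)
#' @export
contingency_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (!all(vapply(cells, is_count, logical(1)))) {
    abort("cells must be nonnegative integers")
  }
  if (sum(cells) == 0) abort("all-zero table rejected")
  structure(as.list(as.integer(cells)), names = names(cells),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- as_matrix_2x2(x)
  cat("contingency_2x2 (rows: marker +/-, cols: exposure +/-)\n")
  print(m)
  invisible(x)
}

as_matrix_2x2 <- function(tab) {
  matrix(c(tab$a, tab$c, tab$b, tab$d), 2L, 2L,
         dimnames = list(marker = c("positive", "negative"),
                         exposure = c("positive", "negative")))
}

# Zero cells make the OR and Woolf variance degenerate; the Haldane-Anscombe
# correction adds 0.5 to every cell, and the method label records that it
# was applied. Complete tables are never touched.
corrected_cells <- function(tab) {
  cells <- c(tab$a, tab$b, tab$c, tab$d)
  if (any(cells == 0L)) {
    list(cells = cells + 0.5, method = "haldane_woolf")
  } else {
    list(cells = as.numeric(cells), method = "woolf")
  }
}

#' Odds ratio of a 2x2 table
#'
#' `(a * d) / (b * c)`; when any cell is zero the Haldane-Anscombe +0.5
#' correction is applied to all four cells first (see
#' `attr(, "method")`).
#'
#' @param table A [contingency_2x2()].
#' @return Positive odds ratio with attribute `method` (`"woolf"` or
#'   `"haldane_woolf"`).
#' @examples
#' odds_ratio(contingency_2x2(28, 21, 9, 20)) # 2.96
#' @export
odds_ratio <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  cc <- corrected_cells(table)
  or <- (cc$cells[1] * cc$cells[4]) / (cc$cells[2] * cc$cells[3])
  structure(or, method = cc$method)
}

#' Woolf confidence interval for the odds ratio
#'
#' The log-normal interval
#' `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`, on Haldane-corrected
#' cells when a zero cell is present.
#'
#' @param table A [contingency_2x2()].
#' @param level Confidence level (default 0.95).
#' @return Named numeric `c(ci_low, ci_high)` with attribute `method`.
#' @examples
#' woolf_ci(contingency_2x2(28, 21, 9, 20)) # (1.12, 7.81)
#' @export
woolf_ci <- function(table, level = 0.95) {
  stopifnot(inherits(table, "contingency_2x2"))
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    abort("level must lie strictly in (0, 1)")
  }
  cc <- corrected_cells(table)
  lor <- log((cc$cells[1] * cc$cells[4]) / (cc$cells[2] * cc$cells[3]))
  se <- sqrt(sum(1 / cc$cells))
  z <- qnorm((1 + level) / 2)
  structure(c(ci_low = exp(lor - z * se), ci_high = exp(lor + z * se)),
            method = cc$method)
}

#' Two-sided association test for a 2x2 table
#'
#' Fisher's exact test (default; two-sided by summing the probabilities of
#' all margin-fixed tables no more probable than the observed one) or the
#' chi-square test with or without Yates continuity correction. For
#' chi-square variants a warning is issued when any expected cell count is
#' below 5.
#'
#' @param table A [contingency_2x2()].
#' @param test `"fisher"`, `"chi2"` or `"chi2_yates"`.
#' @return Two-sided p-value.
#' @export
association_test <- function(table, test = c("fisher", "chi2", "chi2_yates")) {
  stopifnot(inherits(table, "contingency_2x2"))
  test <- match.arg(test)
  m <- as_matrix_2x2(table)
  if (test == "fisher") {
    return(fisher.test(m)$p.value)
  }
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 5)) {
    warning("expected cell count below 5; chi-square approximation is poor",
            call. = FALSE)
  }
  suppressWarnings(
    chisq.test(m, correct = (test == "chi2_yates"))$p.value
  )
}

#' Percent positivity
#'
#' @param count Number of positive samples.
#' @param total Total samples; must be positive.
#' @return `100 * count / total`, rounded to two decimals, as tables of
#'   marker positivity print it.
#' @examples
#' percent_positive(28, 78) # 35.90
#' @export
percent_positive <- function(count, total) {
  if (!is_count(count)) abort("count must be a nonnegative integer")
  if (!is_count(total) || total == 0) abort("total must be a positive integer")
  if (count > total) abort("count cannot exceed total")
  round(100 * count / total, 2)
}

#' Full association summary of a 2x2 table
#'
#' Bundles the odds ratio, Woolf confidence interval and association test
#' into one result row, the record an association table prints per marker
#' pair.
#'
#' @param table A [contingency_2x2()].
#' @param level Confidence level for the interval.
#' @param test Test passed to [association_test()].
#' @return One-row data frame: `a`, `b`, `c`, `d`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value`, `method`, `test`.
#' @examples
#' associate_2x2(contingency_2x2(28, 21, 9, 20))
#' @export
associate_2x2 <- function(table, level = 0.95, test = "fisher") {
  or <- odds_ratio(table)
  ci <- woolf_ci(table, level = level)
  data.frame(
    a = table$a, b = table$b, c = table$c, d = table$d,
    odds_ratio = as.numeric(or),
    ci_low = unname(ci["ci_low"]), ci_high = unname(ci["ci_high"]),
    p_value = association_test(table, test = test),
    method = attr(or, "method"), test = test,
    stringsAsFactors = FALSE
  )
}

#' Packaged marker-positivity fixture
#'
#' Loads the joint TGF-beta1 x B7-H3 and TGF-beta1 x B7-H4 positivity counts
#' from 78 colorectal carcinoma tissues that ship with the package, as a
#' named list of [contingency_2x2()] tables.
#'
#' @return Named list of `contingency_2x2` objects.
#' @export
positivity_fixture <- function() {
  path <- system.file("extdata", "tgfb1_marker_positivity.tsv",
                      package = "crcmirnet", mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    contingency_2x2(df$a[i], df$b[i], df$c[i], df$d[i])
  })
  names(out) <- df$marker
  out
}
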