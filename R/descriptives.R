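#' Weighted frequency distribution of one covariate
#'
#' Level counts are sums of sampling weights; percents are
#' `100 * level_weight / total_weight`, so doubling every weight leaves
#' the percent column unchanged. With unit weights the table equals the
#' unweighted tally.
#'
#' @param ds an `analysis_dataset`.
#' @param covariate covariate name (or the schema's group variable).
#' @return data.frame of class `frequency_table` with columns
#'   `covariate`, `level`, `weighted_count`, `percent`; attribute
#'   `total_n` holds the weighted total.
#' @export
weighted_frequency_table <- function(ds, covariate) {
  stopifnot(inherits(ds, "analysis_dataset"))
  x <- descriptive_column(ds, covariate)
  if (!nlevels(x)) stop("empty level set for '", covariate, "'")
  w <- ds$records$.weight
  wc <- vapply(levels(x), function(l) sum(w[x == l]), numeric(1))
  tot <- sum(w)
  out <- data.frame(covariate = covariate, level = levels(x),
                    weighted_count = unname(wc),
                    percent = unname(100 * wc / tot),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "total_n") <- tot
  class(out) <- c("frequency_table", class(out))
  out
}

# fetch a covariate (or the group variable) as a factor
descriptive_column <- function(ds, covariate) {
  sch <- ds$schema
  if (covariate == sch$group_var) return(ds$records$.group)
  if (!covariate %in% names(sch$covariates))
    stop("'", covariate, "' is not in the schema")
  ds$records[[covariate]]
}

#' Outcome prevalence by level of one covariate
#'
#' Per level: the weighted count of positive outcomes and the weighted
#' prevalence `100 * weighted_positives / weighted_level_total`. The
#' per-covariate chi-square association test (see [pearson_chi2()]) is
#' attached as attribute `chi2`; it is computed on unweighted record
#' counts, the classical Pearson form. A level with zero total weight
#' gets `NA` prevalence and is flagged in the `undefined` column.
#'
#' @param ds an `analysis_dataset`.
#' @param covariate covariate name (or the group variable).
#' @param weighted_chi2 if `TRUE`, compute the chi-square on weighted
#'   counts instead of record counts (off by default; see Details).
#' @return data.frame of class `prevalence_table` with columns
#'   `covariate`, `level`, `outcome_count`, `prevalence_percent`,
#'   `undefined`; attributes `chi2` (list: statistic, df, p_value) and
#'   `overall` (list: outcome_count, prevalence_percent).
#' @export
prevalence_by_level <- function(ds, covariate, weighted_chi2 = FALSE) {
  stopifnot(inherits(ds, "analysis_dataset"))
  x <- descriptive_column(ds, covariate)
  y <- ds$records$.outcome
  w <- ds$records$.weight
  if (anyNA(y)) stop("outcome missing in analysis dataset")

  lev <- levels(x)
  wpos <- vapply(lev, function(l) sum(w[x == l & y == 1L]), numeric(1))
  wtot <- vapply(lev, function(l) sum(w[x == l]), numeric(1))
  undef <- wtot <= 0
  prev <- ifelse(undef, NA_real_, 100 * wpos / wtot)
  out <- data.frame(covariate = covariate, level = lev,
                    outcome_count = unname(wpos),
                    prevalence_percent = unname(prev),
                    undefined = unname(undef),
                    stringsAsFactors = FALSE, row.names = NULL)

  counts <- if (weighted_chi2) {
    cbind(pos = wpos, neg = wtot - wpos)
  } else {
    cbind(pos = vapply(lev, function(l) sum(x == l & y == 1L), numeric(1)),
          neg = vapply(lev, function(l) sum(x == l & y == 0L), numeric(1)))
  }
  keep <- rowSums(counts) > 0
  # association is undefined on a degenerate margin (e.g. an all-zero
  # outcome); report no test rather than fail the whole table
  testable <- sum(keep) >= 2L &&
    all(colSums(counts[keep, , drop = FALSE]) > 0)
  chi2 <- if (testable) pearson_chi2(counts[keep, , drop = FALSE]) else NULL
  attr(out, "chi2") <- chi2
  attr(out, "overall") <- list(outcome_count = sum(w[y == 1L]),
                               prevalence_percent = 100 * wmean(y, w))
  class(out) <- c("prevalence_table", class(out))
  out
}

#' Overall weighted outcome prevalence
#'
#' @param ds an `analysis_dataset`.
#' @return list with `outcome_count` (weighted positives) and
#'   `prevalence_percent`.
#' @export
overall_prevalence <- function(ds) {
  stopifnot(inherits(ds, "analysis_dataset"))
  y <- ds$records$.outcome
  w <- ds$records$.weight
  list(outcome_count = sum(w[y == 1L]),
       prevalence_percent = 100 * wmean(y, w))
}

#' Classical Pearson chi-square test on a contingency table
#'
#' The usual `sum((O - E)^2 / E)` statistic with
#' `df = (rows - 1) * (cols - 1)` and an upper-tail chi-square p-value,
#' computed by [stats::chisq.test()] without continuity correction.
#'
#' @param counts numeric matrix of non-negative cell counts, at least
#'   2 x 2.
#' @return list with `statistic`, `df`, `p_value`.
#' @examples
#' pearson_chi2(matrix(c(1994, 3617, 1634, 6094), 2, byrow = TRUE))
#' @export
pearson_chi2 <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("contingency table must be at least 2 x 2")
  if (any(counts < 0)) stop("negative cell count")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("degenerate margin: a row or column total is zero")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Render a descriptive table as aligned text
#'
#' Percents and chi-square statistics are rounded to one decimal (half
#' away from zero); p-values below 0.001 render as `"< 0.001"`.
#'
#' @param x a `frequency_table` or `prevalence_table`.
#' @param ... unused.
#' @export
print.frequency_table <- function(x, ...) {
  cat(sprintf("%-28s %12s %8s\n", "Level", "Weighted n", "%"))
  for (i in seq_len(nrow(x)))
    cat(sprintf("%-28s %12.0f %8.1f\n", x$level[i],
                round_half_up(x$weighted_count[i]),
                round_half_up(x$percent[i], 1)))
  cat(sprintf("%-28s %12.0f %8.1f\n", "Total",
              round_half_up(attr(x, "total_n")), 100))
  invisible(x)
}

#' @rdname print.frequency_table
#' @export
print.prevalence_table <- function(x, ...) {
  cat(sprintf("%-28s %12s %8s\n", "Level", "Outcome n", "Prev %"))
  for (i in seq_len(nrow(x)))
    cat(sprintf("%-28s %12.0f %8.1f\n", x$level[i],
                round_half_up(x$outcome_count[i]),
                round_half_up(x$prevalence_percent[i], 1)))
  ch <- attr(x, "chi2")
  if (!is.null(ch))
    cat(sprintf("chi-square = %.1f (df %d), p %s\n",
                round_half_up(ch$statistic, 1), ch$df,
                format_p(ch$p_value)))
  invisible(x)
}
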