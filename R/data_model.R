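#' Derive the binary overweight/obesity indicator from BMI
#'
#' Codes body mass index at the conventional overweight threshold:
#' 1 when BMI >= 25 kg/m^2, 0 otherwise. Missing or non-finite BMI
#' yields `NA` (a missing outcome), so the record can be routed to the
#' exclusion step rather than silently dropped. Negative or zero BMI is
#' a data error, not missingness.
#'
#' @param bmi numeric vector of body mass index values (kg/m^2).
#' @return integer vector of 0/1 with `NA` for missing/non-finite BMI.
#' @examples
#' derive_outcome(c(17, 24.99, 25, 31.4, NA))
#' @export
derive_outcome <- function(bmi) {
  bmi <- as.numeric(bmi)
  bad <- is.finite(bmi) & bmi <= 0
  if (any(bad)) stop("non-positive BMI value(s): data error, not missingness")
  out <- ifelse(bmi >= 25, 1L, 0L)
  out[!is.finite(bmi)] <- NA_integer_
  out
}

#' Read a person-level survey table
#'
#' Reads a comma-delimited text file with a header row and validates it
#' against a [covariate_schema()]: character fields are whitespace-trimmed
#' and matched case-sensitively against declared levels, weights must be
#' positive, and the grouping variable must only take the two declared
#' labels. Either a precomputed 0/1 outcome column or a BMI column (or
#' both, if consistent) must be present; a record where both are present
#' but disagree is an error, never a silent preference.
#'
#' @param path CSV file path.
#' @param schema a [covariate_schema()].
#' @return a data.frame of validated raw records (one row per person)
#'   with standardized columns `.id`, `.group`, `.outcome`, `.bmi`,
#'   `.weight`, `.pregnant` plus one factor column per covariate.
#' @export
read_survey_csv <- function(path, schema) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_records(raw, schema)
}

#' Validate raw records against a schema
#'
#' The data.frame method of the reader: applies the same trimming,
#' level-membership, weight and outcome/BMI consistency checks as
#' [read_survey_csv()] to an in-memory table (e.g. one produced by
#' [generate_sample()]).
#'
#' @param df data.frame of raw records.
#' @inheritParams read_survey_csv
#' @return standardized data.frame; see [read_survey_csv()].
#' @export
validate_records <- function(df, schema) {
  stopifnot(inherits(schema, "covariate_schema"))
  trim <- function(x) if (is.character(x)) trimws(x) else x
  df[] <- lapply(df, trim)

  need <- c(schema$group_var, schema$weight_col, names(schema$covariates))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))

  has_outcome <- schema$outcome_col %in% names(df)
  has_bmi <- schema$bmi_col %in% names(df)
  if (!has_outcome && !has_bmi)
    stop("neither outcome column '", schema$outcome_col,
         "' nor BMI column '", schema$bmi_col, "' present")

  n <- nrow(df)
  out <- data.frame(
    .id = if (schema$id_col %in% names(df)) as.character(df[[schema$id_col]])
          else as.character(seq_len(n)),
    stringsAsFactors = FALSE
  )

  grp <- as.character(df[[schema$group_var]])
  bad_grp <- setdiff(unique(grp[!is.na(grp)]), schema$group_levels)
  if (length(bad_grp))
    stop("undeclared group label(s) in '", schema$group_var, "': ",
         paste(bad_grp, collapse = ", "))
  out$.group <- factor(grp, levels = schema$group_levels)

  w <- as.numeric(df[[schema$weight_col]])
  if (any(!is.na(w) & w <= 0)) stop("non-positive sampling weight(s)")
  out$.weight <- w

  bmi <- if (has_bmi) as.numeric(df[[schema$bmi_col]]) else rep(NA_real_, n)
  derived <- if (has_bmi) derive_outcome(bmi) else rep(NA_integer_, n)
  if (has_outcome) {
    yc <- df[[schema$outcome_col]]
    y <- suppressWarnings(as.integer(yc))
    if (any(!is.na(y) & !y %in% c(0L, 1L)))
      stop("outcome column '", schema$outcome_col, "' must be 0/1")
    conflict <- !is.na(y) & !is.na(derived) & y != derived
    if (any(conflict))
      stop(sum(conflict), " record(s) with outcome contradicting BMI ",
           "(supplied outcome and BMI-derived indicator disagree)")
    y[is.na(y)] <- derived[is.na(y)]
  } else {
    y <- derived
  }
  out$.outcome <- y
  out$.bmi <- bmi

  out$.pregnant <- if (schema$pregnant_col %in% names(df)) {
    pg <- suppressWarnings(as.integer(df[[schema$pregnant_col]]))
    if (any(!is.na(pg) & !pg %in% c(0L, 1L))) stop("pregnancy flag must be 0/1")
    pg
  } else rep(0L, n)

  for (nm in names(schema$covariates)) {
    lv <- schema$covariates[[nm]]$levels
    x <- as.character(df[[nm]])
    bad <- setdiff(unique(x[!is.na(x) & x != ""]), lv)
    if (length(bad))
      stop("undeclared level(s) for covariate '", nm, "': ",
           paste(bad, collapse = ", "))
    x[!is.na(x) & x == ""] <- NA
    out[[nm]] <- factor(x, levels = lv)
  }
  out
}

#' Apply the study exclusion rules
#'
#' Removes, in this order and with per-rule counts: records flagged
#' pregnant at interview; records with a missing outcome (missing or
#' non-finite BMI when the outcome is BMI-derived) or missing sampling
#' weight; records with a missing group label or missing covariate
#' values (listwise deletion, counted separately so the two named study
#' rules remain auditable). Surviving record order is preserved.
#'
#' @param records validated records from [read_survey_csv()] /
#'   [validate_records()].
#' @param schema the [covariate_schema()] the records were validated
#'   against.
#' @return an object of class `analysis_dataset`: list with `records`
#'   (clean data.frame), `schema`, `n_raw` and exclusion counts
#'   `n_excluded_pregnant`, `n_excluded_missing`,
#'   `n_excluded_covariate`.
#' @export
apply_exclusions <- function(records, schema) {
  stopifnot(is.data.frame(records), inherits(schema, "covariate_schema"))
  n_raw <- nrow(records)

  preg <- !is.na(records$.pregnant) & records$.pregnant == 1L
  n_preg <- sum(preg)
  kept <- records[!preg, , drop = FALSE]

  miss <- is.na(kept$.outcome) | is.na(kept$.weight)
  n_miss <- sum(miss)
  kept <- kept[!miss, , drop = FALSE]

  cov_cols <- names(schema$covariates)
  miss_cov <- is.na(kept$.group)
  for (nm in cov_cols) miss_cov <- miss_cov | is.na(kept[[nm]])
  n_cov <- sum(miss_cov)
  if (n_cov > 0)
    message(n_cov, " record(s) dropped for missing covariate/group values (listwise)")
  kept <- kept[!miss_cov, , drop = FALSE]

  if (nrow(kept) == 0L) stop("empty analysis set: no records survive the exclusions")
  if (length(unique(kept$.group)) < 2L)
    stop("degenerate grouping: fewer than two group levels after exclusion")

  rownames(kept) <- NULL
  structure(
    list(records = kept, schema = schema, n_raw = n_raw,
         n_excluded_pregnant = n_preg, n_excluded_missing = n_miss,
         n_excluded_covariate = n_cov),
    class = "analysis_dataset"
  )
}

#' @export
print.analysis_dataset <- function(x, ...) {
  cat("Analysis dataset:", nrow(x$records), "records (of", x$n_raw, "raw)\n")
  cat("  excluded: pregnant", x$n_excluded_pregnant,
      "| missing outcome/weight", x$n_excluded_missing,
      "| missing covariate", x$n_excluded_covariate, "\n")
  print(table(x$records$.group))
  invisible(x)
}

#' Build the dummy-coded design matrix
#'
#' One intercept column plus, for each requested covariate, one 0/1
#' indicator column per non-reference level (treatment coding), labelled
#' `"covariate=level"`. Row order matches record order. A declared level
#' absent from the data leaves an all-zero column; it is retained (with
#' a warning) because cross-group counterfactual predictions need both
#' groups' matrices on an identical column layout.
#'
#' @param ds an `analysis_dataset`, or a clean records data.frame.
#' @param covariates character vector of covariate names (default: all
#'   schema covariates, in schema order).
#' @param schema required only when `ds` is a bare data.frame.
#' @return numeric matrix with attributes `covariate`, `level` (per
#'   column) and `reference` (per covariate) describing the layout.
#' @export
encode_design_matrix <- function(ds, covariates = NULL, schema = NULL) {
  if (inherits(ds, "analysis_dataset")) {
    schema <- ds$schema
    rec <- ds$records
  } else {
    stopifnot(inherits(schema, "covariate_schema"))
    rec <- ds
  }
  covariates <- covariates %||% names(schema$covariates)
  unknown <- setdiff(covariates, names(schema$covariates))
  if (length(unknown))
    stop("covariate(s) not in schema: ", paste(unknown, collapse = ", "))

  n <- nrow(rec)
  cols <- list(`(Intercept)` = rep(1, n))
  col_cov <- "(Intercept)"
  col_lev <- ""
  for (nm in covariates) {
    cv <- schema$covariates[[nm]]
    for (lev in setdiff(cv$levels, cv$reference)) {
      cols[[paste0(nm, "=", lev)]] <- as.numeric(rec[[nm]] == lev)
      col_cov <- c(col_cov, nm)
      col_lev <- c(col_lev, lev)
    }
  }
  X <- do.call(cbind, cols)
  empty <- colSums(X) == 0
  if (any(empty))
    warning("all-zero design column(s) retained: ",
            paste(colnames(X)[empty], collapse = ", "))
  attr(X, "covariate") <- col_cov
  attr(X, "level") <- col_lev
  attr(X, "reference") <- vapply(schema$covariates[covariates],
                                 function(cv) cv$reference, character(1))
  X
}

#' Decode one design-matrix row back to category labels
#'
#' Inverse of [encode_design_matrix()] for a single record: maps an
#' indicator row back to the named category of every covariate (the
#' reference level when all of a covariate's indicators are zero).
#'
#' @param row one row of a matrix from [encode_design_matrix()].
#' @param X the design matrix the row came from (for its layout
#'   attributes).
#' @return named character vector of category labels.
#' @export
decode_design_row <- function(row, X) {
  col_cov <- attr(X, "covariate")
  col_lev <- attr(X, "level")
  refs <- attr(X, "reference")
  out <- refs
  for (nm in names(refs)) {
    j <- which(col_cov == nm & row == 1)
    if (length(j) > 1L) stop("invalid indicator row: multiple levels set for '", nm, "'")
    if (length(j) == 1L) out[nm] <- col_lev[j]
  }
  out
}

#' Write a cleaned analysis dataset back to CSV for audit
#'
#' @param ds an `analysis_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_analysis_csv <- function(ds, path) {
  stopifnot(inherits(ds, "analysis_dataset"))
  rec <- ds$records
  sch <- ds$schema
  out <- data.frame(id = rec$.id, stringsAsFactors = FALSE)
  out[[sch$group_var]] <- as.character(rec$.group)
  out[[sch$outcome_col]] <- rec$.outcome
  out[[sch$bmi_col]] <- rec$.bmi
  out[[sch$weight_col]] <- rec$.weight
  for (nm in names(sch$covariates)) out[[nm]] <- as.character(rec[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
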