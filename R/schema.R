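#' Define the covariate schema for an analysis dataset
#'
#' A covariate schema declares, in analysis order, the categorical
#' covariates (levels and reference level), the two-level grouping
#' variable whose outcome gap is decomposed, and the column names of the
#' outcome, BMI, weight, pregnancy-flag and id fields in the input table.
#'
#' The first element of `group_levels` is "group 1" (the urban analogue
#' in a rural-urban disparity analysis): the prevalence gap is defined as
#' group 1 minus group 2, and the default decomposition weights the
#' endowment component by group-2 coefficients.
#'
#' @param covariates named list; each element a list with `levels`
#'   (character vector of category labels, unique) and `reference`
#'   (one of `levels`). Order of the list is the reporting order.
#' @param group_var name of the grouping column.
#' @param group_levels character vector of exactly two labels; first is
#'   group 1.
#' @param outcome_col,bmi_col,weight_col,pregnant_col,id_col column
#'   names used when reading a table. `outcome_col` and `bmi_col` may
#'   both be absent from a file, but not simultaneously.
#' @return an object of class `covariate_schema`.
#' @examples
#' covariate_schema(
#'   covariates = list(
#'     wealth = list(levels = c("poor", "middle", "rich"), reference = "poor"),
#'     media  = list(levels = c("not_exposed", "exposed"), reference = "not_exposed")
#'   ),
#'   group_var = "residence", group_levels = c("urban", "rural")
#' )
#' @export
covariate_schema <- function(covariates, group_var, group_levels,
                             outcome_col = "outcome", bmi_col = "bmi",
                             weight_col = "weight", pregnant_col = "pregnant",
                             id_col = "id") {
  stopifnot(is.list(covariates), length(covariates) >= 1L)
  nms <- names(covariates)
  if (is.null(nms) || anyNA(nms) || any(nms == "") || anyDuplicated(nms))
    stop("covariates must be a uniquely named list")
  for (nm in nms) {
    cv <- covariates[[nm]]
    if (!is.list(cv) || is.null(cv$levels) || is.null(cv$reference))
      stop("covariate '", nm, "' needs 'levels' and 'reference'")
    cv$levels <- as.character(cv$levels)
    if (anyDuplicated(cv$levels))
      stop("covariate '", nm, "' has duplicated levels")
    if (length(cv$levels) < 2L)
      stop("covariate '", nm, "' needs at least two levels")
    if (!cv$reference %in% cv$levels)
      stop("reference '", cv$reference, "' is not a level of covariate '", nm, "'")
    covariates[[nm]] <- list(levels = cv$levels, reference = as.character(cv$reference))
  }
  group_levels <- as.character(group_levels)
  if (length(group_levels) != 2L || anyDuplicated(group_levels))
    stop("group_levels must be exactly two distinct labels")
  structure(
    list(covariates = covariates, group_var = group_var,
         group_levels = group_levels, outcome_col = outcome_col,
         bmi_col = bmi_col, weight_col = weight_col,
         pregnant_col = pregnant_col, id_col = id_col),
    class = "covariate_schema"
  )
}

#' @export
print.covariate_schema <- function(x, ...) {
  cat("Covariate schema\n")
  cat("  group:", x$group_var, "=", paste(x$group_levels, collapse = " vs "), "\n")
  for (nm in names(x$covariates)) {
    cv <- x$covariates[[nm]]
    lev <- cv$levels
    lev[lev == cv$reference] <- paste0("[", cv$reference, "]")
    cat("  ", nm, ": ", paste(lev, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Read or write a covariate schema as JSON
#'
#' The on-disk form mirrors the constructor arguments so a schema file
#' fully determines how a CSV is interpreted.
#'
#' @param path file path.
#' @return `read_schema_json()` returns a `covariate_schema`;
#'   `write_schema_json()` returns `path` invisibly.
#' @export
read_schema_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  covs <- lapply(raw$covariates, function(cv)
    list(levels = as.character(cv$levels), reference = as.character(cv$reference)))
  covariate_schema(
    covariates = covs, group_var = raw$group_var,
    group_levels = as.character(raw$group_levels),
    outcome_col = raw$outcome_col %||% "outcome",
    bmi_col = raw$bmi_col %||% "bmi",
    weight_col = raw$weight_col %||% "weight",
    pregnant_col = raw$pregnant_col %||% "pregnant",
    id_col = raw$id_col %||% "id"
  )
}

#' @rdname read_schema_json
#' @param schema a `covariate_schema`.
#' @export
write_schema_json <- function(schema, path) {
  stopifnot(inherits(schema, "covariate_schema"))
  jsonlite::write_json(unclass(schema), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
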