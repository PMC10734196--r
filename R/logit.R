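# Core IRLS wrapper: binomial glm.fit on an explicit design matrix.
# Kept separate from the user-facing constructor so the bootstrap can
# refit thousands of resamples with warm starts and no re-validation.
fit_logit_matrix <- function(X, y, w, start = NULL,
                             epsilon = 1e-12, maxit = 100L) {
  fit <- withCallingHandlers(
    stats::glm.fit(x = X, y = y, weights = w, start = start,
                   family = stats::binomial(),
                   control = stats::glm.control(epsilon = epsilon,
                                                maxit = maxit)),
    warning = function(wn) {
      if (grepl("non-integer", conditionMessage(wn)))
        invokeRestart("muffleWarning")
    }
  )
  fit
}

#' Fit a survey-weighted logistic regression
#'
#' Maximizes the weight-multiplied Bernoulli log-likelihood
#' `sum_i w_i [y_i log p_i + (1 - y_i) log(1 - p_i)]` with
#' `logit(p_i) = x_i' beta`, by iteratively reweighted least squares
#' (binomial IRLS, relative-deviance tolerance 1e-12, at most 100
#' iterations). The reported `converged` flag additionally requires the
#' score to vanish: `max |X' diag(w) (y - p)| < 1e-6 * sum(w)`.
#'
#' Weights enter as frequency-style weights in both the score and the
#' information, so point estimates match survey-weighted estimation;
#' the covariance (inverse weighted information) then depends on the
#' weight scale, and weights are normalized to mean 1 over the fitted
#' subset by default to keep reported intervals comparable across weight
#' scales. Coefficients are invariant to any rescaling of the weights.
#'
#' @param ds an `analysis_dataset`.
#' @param covariates covariate names to enter (default: all, in schema
#'   order).
#' @param subset optional group label: fit on that subsample only.
#' @param normalize_weights normalize weights to mean 1 on the fitted
#'   subset (default `TRUE`).
#' @return an object of class `logit_fit`: `coefficients`, `vcov`
#'   (inverse weighted information), `column_labels`, `converged`,
#'   `n_iter`, `log_likelihood`, `group_tag`, `n`, plus the design
#'   layout needed to label odds-ratio tables.
#' @export
fit_weighted_logit <- function(ds, covariates = NULL, subset = NULL,
                               normalize_weights = TRUE) {
  stopifnot(inherits(ds, "analysis_dataset"))
  covariates <- covariates %||% names(ds$schema$covariates)
  rec <- ds$records
  if (!is.null(subset)) {
    if (!subset %in% ds$schema$group_levels)
      stop("unknown group label '", subset, "'")
    rec <- rec[rec$.group == subset, , drop = FALSE]
    if (!nrow(rec)) stop("empty subsample for group '", subset, "'")
  }
  X <- suppressWarnings(
    encode_design_matrix(rec, covariates, schema = ds$schema))
  y <- rec$.outcome
  w <- rec$.weight
  if (normalize_weights) w <- w / mean(w)

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }

  fit <- fit_logit_matrix(X, y, w)
  beta <- fit$coefficients
  mu <- fit$fitted.values
  score <- drop(crossprod(X, w * (y - mu)))
  converged <- fit$converged && max(abs(score)) < 1e-6 * sum(w)
  # diverging coefficients with either a non-converged likelihood or
  # fitted probabilities saturated at 0/1 signal (quasi-)separation
  if (any(abs(beta) > 15) &&
      (!fit$converged || min(mu * (1 - mu)) < 1e-10))
    stop("quasi-separation: coefficient(s) beyond 15 on the logit scale ",
         "with a degenerate likelihood")

  info <- crossprod(X, X * (w * mu * (1 - mu)))
  vc <- chol2inv(chol(info))
  dimnames(vc) <- list(colnames(X), colnames(X))
  ll <- sum(w * (y * log(pmax(mu, 1e-300)) +
                 (1 - y) * log(pmax(1 - mu, 1e-300))))

  structure(
    list(coefficients = beta, vcov = vc, column_labels = colnames(X),
         converged = converged, n_iter = fit$iter, log_likelihood = ll,
         group_tag = subset %||% "all", n = nrow(rec), weight_sum = sum(w),
         covariate = attr(X, "covariate"), level = attr(X, "level"),
         reference = attr(X, "reference"), covariates = covariates),
    class = "logit_fit"
  )
}

#' @export
print.logit_fit <- function(x, ...) {
  cat("Weighted logistic fit (", x$group_tag, "): n = ", x$n,
      ", iterations = ", x$n_iter,
      if (x$converged) ", converged" else ", NOT converged", "\n", sep = "")
  se <- sqrt(diag(x$vcov))
  tab <- data.frame(estimate = x$coefficients, se = se,
                    z = x$coefficients / se)
  print(round(tab, 4))
  invisible(x)
}

#' Odds-ratio table from a fitted weighted logit
#'
#' `OR = exp(beta)` with Wald confidence limits
#' `exp(beta +/- z * se)` and two-sided Wald p-values. Reference levels
#' are included as rows with `OR = 1` and empty interval, mirroring the
#' conventional regression-table layout.
#'
#' @param fit a converged `logit_fit`.
#' @param alpha two-sided level (default 0.05 for 95% intervals).
#' @return data.frame of class `or_table`: `covariate`, `level`, `OR`,
#'   `CI_low`, `CI_high`, `p_value`, `is_reference`.
#' @export
odds_ratio_table <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "logit_fit"))
  if (!fit$converged) stop("fit did not converge; refusing to tabulate")
  z <- stats::qnorm(1 - alpha / 2)
  se <- sqrt(diag(fit$vcov))
  rows <- list()
  for (nm in fit$covariates) {
    ref <- fit$reference[[nm]]
    rows[[length(rows) + 1L]] <- data.frame(
      covariate = nm, level = ref, OR = 1, CI_low = NA_real_,
      CI_high = NA_real_, p_value = NA_real_, is_reference = TRUE,
      stringsAsFactors = FALSE)
    idx <- which(fit$covariate == nm)
    for (j in idx) {
      b <- fit$coefficients[j]
      s <- se[j]
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = nm, level = fit$level[j], OR = exp(b),
        CI_low = exp(b - z * s), CI_high = exp(b + z * s),
        p_value = 2 * stats::pnorm(-abs(b / s)), is_reference = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("or_table", class(out))
  out
}

#' @export
print.or_table <- function(x, ...) {
  cat(sprintf("%-16s %-20s %s\n", "Covariate", "Level", "OR (95% CI)"))
  for (i in seq_len(nrow(x))) {
    cell <- if (x$is_reference[i]) "1" else
      sprintf("%.2f (%.2f-%.2f)%s", round_half_up(x$OR[i], 2),
              round_half_up(x$CI_low[i], 2), round_half_up(x$CI_high[i], 2),
              p_stars(x$p_value[i]))
    cat(sprintf("%-16s %-20s %s\n", x$covariate[i], x$level[i], cell))
  }
  invisible(x)
}

#' Unadjusted odds-ratio sweep over all covariates
#'
#' Fits one single-covariate weighted logit per schema entry and
#' concatenates the per-model odds-ratio tables in schema order — the
#' conventional "unadjusted OR" column of an epidemiological regression
#' table. The companion adjusted column is [odds_ratio_table()] applied
#' to the full multivariable fit.
#'
#' @param ds an `analysis_dataset`.
#' @param alpha two-sided level.
#' @return an `or_table` data.frame spanning all covariates.
#' @export
unadjusted_or_sweep <- function(ds, alpha = 0.05) {
  stopifnot(inherits(ds, "analysis_dataset"))
  tabs <- lapply(names(ds$schema$covariates), function(nm)
    odds_ratio_table(fit_weighted_logit(ds, covariates = nm), alpha = alpha))
  out <- do.call(rbind, tabs)
  class(out) <- c("or_table", class(out))
  out
}
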