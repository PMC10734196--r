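#' Threefold decomposition algebra on the linear index
#'
#' The classical threefold split of a mean-outcome gap, from the
#' viewpoint of group 2 (the disadvantaged/rural analogue): with
#' group-specific coefficient vectors `beta1`, `beta2` and mean design
#' vectors `xbar1`, `xbar2` (first element the intercept),
#' \deqn{E = \sum_j \beta^2_j (\bar x^1_j - \bar x^2_j), \quad
#'       C = \sum_j \bar x^2_j (\beta^1_j - \beta^2_j) +
#'           (\beta^1_0 - \beta^2_0), \quad
#'       I = \sum_j (\bar x^1_j - \bar x^2_j)(\beta^1_j - \beta^2_j)}
#' so that `E + C + I` equals the gap `xbar1'beta1 - xbar2'beta2`
#' exactly by algebra. `B`, the intercept difference
#' `beta1_0 - beta2_0`, is the share of `C` attributable to
#' unobservables; it is reported separately but folded inside `C`.
#'
#' @param beta1,beta2 named coefficient vectors whose first element is
#'   `"(Intercept)"`, identical layouts.
#' @param xbar1,xbar2 mean design vectors on the same layout
#'   (intercept element 1).
#' @return named numeric vector `c(D, E, C, I, B)` on the linear-index
#'   scale.
#' @examples
#' b1 <- c("(Intercept)" = 0, x = 1.5)
#' b2 <- c("(Intercept)" = 0, x = 1.0)
#' threefold_components(b1, b2, c(1, 0.6), c(1, 0.4))  # E=.2 C=.2 I=.1
#' @export
threefold_components <- function(beta1, beta2, xbar1, xbar2) {
  stopifnot(length(beta1) == length(beta2),
            length(xbar1) == length(beta1),
            length(xbar2) == length(beta1))
  s <- seq_along(beta1)[-1]                      # slope positions
  E <- sum(beta2[s] * (xbar1[s] - xbar2[s]))
  B <- unname(beta1[1] - beta2[1])
  C <- sum(xbar2[s] * (beta1[s] - beta2[s])) + B
  I <- sum((xbar1[s] - xbar2[s]) * (beta1[s] - beta2[s]))
  c(D = E + C + I, E = E, C = C, I = I, B = B)
}

# per-column detailed parts; contrast "reference" reports the encoded
# (non-reference) columns as-is, "deviation" re-expresses each
# covariate's coefficients as deviations from their level mean so the
# parts no longer depend on the omitted category (all levels get a row)
detail_parts <- function(lb1, lb2, xbar1, xbar2, layout,
                         contrast = c("reference", "deviation")) {
  contrast <- match.arg(contrast)
  rows <- list()
  if (contrast == "reference") {
    for (j in seq_along(lb1)[-1]) {
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = layout$covariate[j], level = layout$level[j],
        E_part = unname(lb2[j] * (xbar1[j] - xbar2[j])),
        C_part = unname(xbar2[j] * (lb1[j] - lb2[j])),
        stringsAsFactors = FALSE)
    }
    constant <- unname(lb1[1] - lb2[1])
  } else {
    shift1 <- 0; shift2 <- 0
    for (nm in names(layout$full_levels)) {
      levs <- layout$full_levels[[nm]]
      ref <- layout$reference[[nm]]
      bf <- function(lb) {
        b <- stats::setNames(rep(0, length(levs)), levs)
        j <- which(layout$covariate == nm)
        b[layout$level[j]] <- lb[j]
        b
      }
      pf <- function(xb) {
        p <- stats::setNames(rep(0, length(levs)), levs)
        j <- which(layout$covariate == nm)
        p[layout$level[j]] <- xb[j]
        p[ref] <- 1 - sum(p)
        p
      }
      b1 <- bf(lb1); b2 <- bf(lb2)
      p1 <- pf(xbar1); p2 <- pf(xbar2)
      m1 <- mean(b1); m2 <- mean(b2)
      shift1 <- shift1 + m1; shift2 <- shift2 + m2
      for (l in levs) {
        rows[[length(rows) + 1L]] <- data.frame(
          covariate = nm, level = l,
          E_part = unname((b2[l] - m2) * (p1[l] - p2[l])),
          C_part = unname(p2[l] * ((b1[l] - m1) - (b2[l] - m2))),
          stringsAsFactors = FALSE)
      }
    }
    constant <- unname((lb1[1] + shift1) - (lb2[1] + shift2))
  }
  list(rows = do.call(rbind, rows), constant = constant)
}

# engine shared by threefold_decompose() and the bootstrap: operates on
# a pre-encoded design so resamples never re-encode
decompose_core <- function(X, y, w, g1, layout,
                           mode = "logit_counterfactual",
                           start1 = NULL, start2 = NULL) {
  i1 <- g1
  i2 <- !g1
  if (!any(i1) || !any(i2)) stop("a group is empty")
  X1 <- X[i1, , drop = FALSE]; y1 <- y[i1]; w1 <- w[i1] / mean(w[i1])
  X2 <- X[i2, , drop = FALSE]; y2 <- y[i2]; w2 <- w[i2] / mean(w[i2])
  xbar1 <- colSums(X1 * w1) / sum(w1)
  xbar2 <- colSums(X2 * w2) / sum(w2)

  lf1 <- stats::lm.wfit(X1, y1, w1)
  lf2 <- stats::lm.wfit(X2, y2, w2)
  lb1 <- lf1$coefficients
  lb2 <- lf2$coefficients
  if (anyNA(lb1) || anyNA(lb2))
    stop("rank-deficient group design in linear-probability fit")
  lin <- threefold_components(lb1, lb2, xbar1, xbar2)

  if (mode == "linear") {
    mean1 <- sum(w1 * y1) / sum(w1)
    mean2 <- sum(w2 * y2) / sum(w2)
    comps <- c(D = mean1 - mean2, E = unname(lin["E"]),
               C = unname(lin["C"]), I = unname(lin["I"]),
               B = unname(lin["B"]))
    gb1 <- lb1; gb2 <- lb2
  } else {
    f1 <- fit_logit_matrix(X1, y1, w1, start = start1)
    f2 <- fit_logit_matrix(X2, y2, w2, start = start2)
    if (!f1$converged || !f2$converged) stop("group logit fit did not converge")
    gb1 <- f1$coefficients
    gb2 <- f2$coefficients
    pbar <- function(Xa, wa, b) sum(wa * stats::plogis(drop(Xa %*% b))) / sum(wa)
    P11 <- pbar(X1, w1, gb1)
    P12 <- pbar(X1, w1, gb2)
    P21 <- pbar(X2, w2, gb1)
    P22 <- pbar(X2, w2, gb2)
    b_swap <- gb2
    b_swap[1] <- gb1[1]
    P2s <- pbar(X2, w2, b_swap)
    E <- P12 - P22
    C <- P21 - P22
    comps <- c(D = P11 - P22, E = E, C = C, I = P11 - P22 - E - C,
               B = P2s - P22)
    mean1 <- P11
    mean2 <- P22
  }

  list(components = comps, mean1 = mean1, mean2 = mean2,
       lin_beta1 = lb1, lin_beta2 = lb2, beta1 = gb1, beta2 = gb2,
       xbar1 = xbar1, xbar2 = xbar2, lin = lin)
}

make_layout <- function(X, schema, covariates) {
  list(covariate = attr(X, "covariate"), level = attr(X, "level"),
       reference = attr(X, "reference"),
       full_levels = lapply(schema$covariates[covariates], `[[`, "levels"))
}

#' Threefold decomposition of the group gap in outcome prevalence
#'
#' Splits the difference in weighted outcome prevalence between the two
#' groups (group 1 minus group 2) into endowment (E), coefficient (C)
#' and interaction (I) components, from the group-2 viewpoint: E is the
#' part of the gap explained by group differences in covariate levels
#' valued at group-2 coefficients; C the part due to differences in
#' coefficients valued at group-2 covariate means, including the
#' intercept ("unobservables") difference B; I their joint product.
#'
#' Two modes:
#' * `"logit_counterfactual"` (default for headline numbers): fits a
#'   weighted logit per group and evaluates counterfactual mean
#'   predictions; `E = P(X1,b2) - P(X2,b2)`, `C = P(X2,b1) - P(X2,b2)`,
#'   `I = D - E - C` (residual-defined, so `E + C + I = D` exactly).
#'   Because each group model contains an intercept, the group mean
#'   predictions equal the weighted observed prevalences.
#' * `"linear"`: weighted least-squares linear-probability fits per
#'   group and the classical summation formulas of
#'   [threefold_components()], where the additive identity holds by
#'   algebra and the per-covariate detailed parts are exact.
#'
#' @param ds an `analysis_dataset`.
#' @param covariates covariates to enter (default: all).
#' @param mode `"logit_counterfactual"` or `"linear"`.
#' @param reference_group viewpoint: the group whose coefficients value
#'   the endowment component. Default is group 2 (the second schema
#'   group level); passing the group-1 label swaps the viewpoint.
#' @return an object of class `oaxaca_decomposition` holding
#'   `mean_pred_group1/2`, `D`, `E`, `C`, `I`, `B`, percent
#'   contributions (`NA` when `|D| < 1e-12`, with a warning), the
#'   group-specific coefficient vectors and weighted design means used,
#'   and the layout needed by [detailed_contributions()].
#' @export
threefold_decompose <- function(ds, covariates = NULL,
                                mode = c("logit_counterfactual", "linear"),
                                reference_group = NULL) {
  stopifnot(inherits(ds, "analysis_dataset"))
  mode <- match.arg(mode)
  covariates <- covariates %||% names(ds$schema$covariates)
  glv <- ds$schema$group_levels
  reference_group <- reference_group %||% glv[2]
  if (!reference_group %in% glv)
    stop("reference_group must be one of: ", paste(glv, collapse = ", "))
  # viewpoint swap: make the non-reference group "group 1"
  lead <- setdiff(glv, reference_group)

  rec <- ds$records
  X <- suppressWarnings(encode_design_matrix(rec, covariates,
                                             schema = ds$schema))
  layout <- make_layout(X, ds$schema, covariates)
  g1 <- rec$.group == lead
  core <- decompose_core(X, rec$.outcome, rec$.weight, g1, layout, mode)

  comps <- core$components
  D <- comps[["D"]]
  pct <- if (abs(D) < 1e-12) {
    warning("gap D is numerically zero; percent contributions undefined")
    c(E = NA_real_, C = NA_real_, I = NA_real_)
  } else {
    c(E = 100 * comps[["E"]] / D, C = 100 * comps[["C"]] / D,
      I = 100 * comps[["I"]] / D)
  }

  structure(
    list(mean_pred_group1 = core$mean1, mean_pred_group2 = core$mean2,
         D = D, E = comps[["E"]], C = comps[["C"]], I = comps[["I"]],
         B = comps[["B"]], pct_E = pct[["E"]], pct_C = pct[["C"]],
         pct_I = pct[["I"]], mode = mode,
         group1 = lead, group2 = reference_group,
         reference_group = reference_group,
         beta1 = core$beta1, beta2 = core$beta2,
         lin_beta1 = core$lin_beta1, lin_beta2 = core$lin_beta2,
         xbar1 = core$xbar1, xbar2 = core$xbar2, lin = core$lin,
         layout = layout, covariates = covariates, ci = NULL),
    class = "oaxaca_decomposition"
  )
}

#' @export
print.oaxaca_decomposition <- function(x, ...) {
  cat("Threefold decomposition (", x$mode, "), viewpoint of ",
      x$reference_group, "\n", sep = "")
  cat(sprintf("  mean prediction %s: %.4f   %s: %.4f\n",
              x$group1, x$mean_pred_group1, x$group2, x$mean_pred_group2))
  rows <- data.frame(
    coefficient = c(x$D, x$E, x$C, x$I),
    pct_of_D = c(100, x$pct_E, x$pct_C, x$pct_I),
    row.names = c("Difference (D)", "Endowment (E)", "Coefficient (C)",
                  "Interaction (I)"))
  if (!is.null(x$ci)) {
    m <- match(c("D", "E", "C", "I"), x$ci$component_ci$component)
    rows$ci_low <- x$ci$component_ci$low[m]
    rows$ci_high <- x$ci$component_ci$high[m]
  }
  print(round(rows, 4))
  cat(sprintf("  intercept share of C (B): %+.4f\n", x$B))
  invisible(x)
}

#' Detailed per-covariate-level contributions
#'
#' Allocates the endowment and coefficient components to individual
#' covariate levels: for encoded column j,
#' `E_part = beta2_j * (xbar1_j - xbar2_j)` and
#' `C_part = xbar2_j * (beta1_j - beta2_j)`, with the intercept
#' difference reported as the `Constant` row of C. The per-part algebra
#' is linear, so parts come from the group-specific linear-probability
#' coefficients; when the decomposition was run in
#' `"logit_counterfactual"` mode, each block of parts is rescaled by a
#' single global factor so it sums to the counterfactual-mode aggregate
#' (the within-block shares are unchanged).
#'
#' Detailed contributions of dummy variables depend on the omitted
#' category. `contrast = "reference"` (default) reports the encoded
#' non-reference rows exactly as fitted; `contrast = "deviation"`
#' re-expresses each covariate's coefficients as deviations from their
#' unweighted level mean, which removes the reference dependence and
#' gives every level (including the reference) a row — for a binary
#' covariate the two rows then carry equal endowment parts.
#'
#' @param decomp an `oaxaca_decomposition`.
#' @param contrast `"reference"` or `"deviation"`.
#' @return data.frame of class `detailed_contribution` with columns
#'   `covariate`, `level`, `E_part`, `E_pct`, `C_part`, `C_pct`; the
#'   final `Constant` row carries the intercept C-part. Percents are
#'   `100 * part / D` (`NA` when `|D| < 1e-12`).
#' @export
detailed_contributions <- function(decomp,
                                   contrast = c("reference", "deviation")) {
  stopifnot(inherits(decomp, "oaxaca_decomposition"))
  contrast <- match.arg(contrast)
  dp <- detail_parts(decomp$lin_beta1, decomp$lin_beta2,
                     decomp$xbar1, decomp$xbar2, decomp$layout, contrast)
  rows <- dp$rows
  constant <- dp$constant

  if (decomp$mode == "logit_counterfactual") {
    sE <- sum(rows$E_part)
    sC <- sum(rows$C_part) + constant
    fE <- if (abs(sE) > 1e-10) decomp$E / sE else 1
    fC <- if (abs(sC) > 1e-10) decomp$C / sC else 1
    rows$E_part <- rows$E_part * fE
    rows$C_part <- rows$C_part * fC
    constant <- constant * fC
  }

  out <- rbind(rows,
               data.frame(covariate = "Constant", level = "",
                          E_part = NA_real_, C_part = constant,
                          stringsAsFactors = FALSE))
  D <- decomp$D
  if (abs(D) < 1e-12) {
    out$E_pct <- NA_real_
    out$C_pct <- NA_real_
  } else {
    out$E_pct <- 100 * out$E_part / D
    out$C_pct <- 100 * out$C_part / D
  }
  out <- out[, c("covariate", "level", "E_part", "E_pct", "C_part", "C_pct")]
  rownames(out) <- NULL
  attr(out, "contrast") <- contrast
  attr(out, "mode") <- decomp$mode
  attr(out, "D") <- D
  class(out) <- c("detailed_contribution", class(out))
  out
}

#' @export
print.detailed_contribution <- function(x, ...) {
  cat(sprintf("%-14s %-18s %10s %7s %10s %7s\n",
              "Covariate", "Level", "E part", "E %", "C part", "C %"))
  fm <- function(v, d) ifelse(is.na(v), "", sprintf(paste0("%.", d, "f"),
                                                    round_half_up(v, d)))
  for (i in seq_len(nrow(x)))
    cat(sprintf("%-14s %-18s %10s %7s %10s %7s\n", x$covariate[i],
                x$level[i], fm(x$E_part[i], 4), fm(x$E_pct[i], 1),
                fm(x$C_part[i], 4), fm(x$C_pct[i], 1)))
  invisible(x)
}

#' Percent contribution of a component to the gap
#'
#' `100 * part / D`, sign-preserving: negative contributions and values
#' beyond 100 are meaningful (a part that widens the gap when removed).
#'
#' @param part component or detailed-part value.
#' @param D the total gap; must be nonzero.
#' @return percent contribution.
#' @examples
#' percent_contribution(0.123, 0.144)  # 85.4
#' @export
percent_contribution <- function(part, D) {
  if (any(!is.finite(D)) || any(D == 0))
    stop("percent contribution undefined: D is zero")
  100 * part / D
}

#' Bootstrap confidence intervals for decomposition components
#'
#' Nonparametric bootstrap of the full decomposition: records are
#' resampled with replacement — within group by default (stratified), so
#' both group fits always have data — the decomposition re-estimated on
#' each replicate, and percentile intervals taken component-wise, for
#' D/E/C/I/B and for every detailed part (including the Constant row).
#' Replicates whose group fits fail to converge are logged and skipped;
#' more than 20% failures aborts.
#'
#' @param ds an `analysis_dataset`.
#' @param covariates covariates to enter (default: all).
#' @param mode decomposition mode, as in [threefold_decompose()].
#' @param B number of bootstrap replicates (>= 100).
#' @param seed integer seed; fixed seed gives identical intervals.
#' @param stratified resample within group (default `TRUE`).
#' @param conf interval level (default 0.95).
#' @param contrast detailed-part contrast, as in
#'   [detailed_contributions()].
#' @param reference_group viewpoint, as in [threefold_decompose()].
#' @return an object of class `decomposition_ci`: `component_ci`
#'   (component, low, high, se), `detail_ci` (covariate, level,
#'   E_low/E_high, C_low/C_high), `n_fail`, `B`, `conf`.
#' @export
bootstrap_cis <- function(ds, covariates = NULL,
                          mode = c("logit_counterfactual", "linear"),
                          B = 200, seed = 1L, stratified = TRUE,
                          conf = 0.95, contrast = c("reference", "deviation"),
                          reference_group = NULL) {
  stopifnot(inherits(ds, "analysis_dataset"), B >= 100)
  mode <- match.arg(mode)
  contrast <- match.arg(contrast)
  covariates <- covariates %||% names(ds$schema$covariates)
  glv <- ds$schema$group_levels
  reference_group <- reference_group %||% glv[2]
  lead <- setdiff(glv, reference_group)

  rec <- ds$records
  X <- suppressWarnings(encode_design_matrix(rec, covariates,
                                             schema = ds$schema))
  layout <- make_layout(X, ds$schema, covariates)
  y <- rec$.outcome
  w <- rec$.weight
  g1 <- rec$.group == lead
  n <- length(y)
  i1 <- which(g1)
  i2 <- which(!g1)

  # warm starts from the full-sample fits cut replicate IRLS iterations
  full <- decompose_core(X, y, w, g1, layout, mode)
  start1 <- if (mode == "logit_counterfactual") full$beta1 else NULL
  start2 <- if (mode == "logit_counterfactual") full$beta2 else NULL
  dp0 <- detail_parts(full$lin_beta1, full$lin_beta2, full$xbar1,
                      full$xbar2, layout, contrast)
  ndetail <- nrow(dp0$rows)

  set.seed(seed)
  comp_mat <- matrix(NA_real_, B, 5,
                     dimnames = list(NULL, c("D", "E", "C", "I", "B")))
  Emat <- matrix(NA_real_, B, ndetail)
  Cmat <- matrix(NA_real_, B, ndetail + 1L)  # + Constant
  n_fail <- 0L
  for (b in seq_len(B)) {
    idx <- if (stratified) {
      c(sample(i1, length(i1), replace = TRUE),
        sample(i2, length(i2), replace = TRUE))
    } else {
      sample.int(n, n, replace = TRUE)
    }
    res <- tryCatch({
      core <- decompose_core(X[idx, , drop = FALSE], y[idx], w[idx],
                             g1[idx], layout, mode,
                             start1 = start1, start2 = start2)
      dp <- detail_parts(core$lin_beta1, core$lin_beta2, core$xbar1,
                         core$xbar2, layout, contrast)
      Ep <- dp$rows$E_part
      Cp <- dp$rows$C_part
      Ct <- dp$constant
      if (mode == "logit_counterfactual") {
        sE <- sum(Ep); sC <- sum(Cp) + Ct
        if (abs(sE) > 1e-10) Ep <- Ep * core$components[["E"]] / sE
        fC <- if (abs(sC) > 1e-10) core$components[["C"]] / sC else 1
        Cp <- Cp * fC; Ct <- Ct * fC
      }
      list(comp = core$components, Ep = Ep, Cp = c(Cp, Ct))
    }, error = function(e) NULL)
    if (is.null(res)) {
      n_fail <- n_fail + 1L
      next
    }
    comp_mat[b, ] <- res$comp
    Emat[b, ] <- res$Ep
    Cmat[b, ] <- res$Cp
  }
  if (n_fail > 0.2 * B)
    stop("unstable resampling: ", n_fail, " of ", B, " replicates failed")

  a <- (1 - conf) / 2
  qs <- function(m) t(apply(m, 2, stats::quantile,
                            probs = c(a, 1 - a), na.rm = TRUE, names = FALSE))
  cq <- qs(comp_mat)
  component_ci <- data.frame(
    component = colnames(comp_mat), low = cq[, 1], high = cq[, 2],
    se = apply(comp_mat, 2, stats::sd, na.rm = TRUE),
    stringsAsFactors = FALSE, row.names = NULL)
  Eq <- qs(Emat)
  Cq <- qs(Cmat)
  detail_ci <- data.frame(
    covariate = c(dp0$rows$covariate, "Constant"),
    level = c(dp0$rows$level, ""),
    E_low = c(Eq[, 1], NA), E_high = c(Eq[, 2], NA),
    C_low = Cq[, 1], C_high = Cq[, 2],
    stringsAsFactors = FALSE, row.names = NULL)

  structure(
    list(component_ci = component_ci, detail_ci = detail_ci,
         n_fail = n_fail, B = B, conf = conf, mode = mode,
         contrast = contrast, seed = seed, stratified = stratified),
    class = "decomposition_ci"
  )
}

#' @export
print.decomposition_ci <- function(x, ...) {
  cat("Bootstrap ", 100 * x$conf, "% percentile intervals (B = ", x$B,
      if (x$stratified) ", stratified" else "", "; ", x$n_fail,
      " failed replicates)\n", sep = "")
  tab <- x$component_ci
  tab[, c("low", "high", "se")] <- round(tab[, c("low", "high", "se")], 4)
  print(tab, row.names = FALSE)
  invisible(x)
}
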