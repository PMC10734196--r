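#' Configure the synthetic two-group survey generator
#'
#' Defines a DHS-like data-generating process: a population split
#' between two groups (urban/rural analogue), independent categorical
#' covariates whose level mixes differ by group, and a group-specific
#' logistic model linking the dummy-coded covariates to a Bernoulli
#' outcome. Because the process is fully known, the true decomposition
#' components can be computed by [compute_truth()] and every downstream
#' estimator validated against them.
#'
#' @param n total sample size.
#' @param p_group1 probability a record belongs to group 1.
#' @param covariates named list; per covariate a list with `levels`,
#'   `reference`, and per-group level-probability vectors `mix1` and
#'   `mix2` (each summing to 1 within 1e-12, aligned with `levels`).
#' @param beta1,beta2 named numeric coefficient vectors on the
#'   dummy-coded design, including `"(Intercept)"`; names and order must
#'   be identical across groups and match the
#'   [encode_design_matrix()] layout (`"covariate=level"` for every
#'   non-reference level).
#' @param weight_shape,weight_scale shape/scale of the gamma sampling
#'   weight distribution; defaults give mean 1.
#' @param group2_weight_scale multiplier applied to group-2 weights
#'   (default 1). Setting it away from 1 makes the weight distribution
#'   group-dependent, to exercise weighted estimators.
#' @param pregnancy_rate,missing_bmi_rate fractions in `[0,1]` of
#'   records flagged pregnant / given a missing BMI, independently of
#'   everything else (so exclusions do not shift the estimand).
#' @param group_var,group_levels labels used in the emitted table.
#' @param seed integer seed; the whole sample is reproducible from it.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n, p_group1, covariates, beta1, beta2,
                             weight_shape = 4, weight_scale = 0.25,
                             group2_weight_scale = 1,
                             pregnancy_rate = 0, missing_bmi_rate = 0,
                             group_var = "residence",
                             group_levels = c("urban", "rural"),
                             seed = 1L) {
  stopifnot(n >= 1, p_group1 > 0, p_group1 < 1,
            pregnancy_rate >= 0, pregnancy_rate <= 1,
            missing_bmi_rate >= 0, missing_bmi_rate <= 1,
            weight_shape > 0, weight_scale > 0, group2_weight_scale > 0)
  expected <- "(Intercept)"
  for (nm in names(covariates)) {
    cv <- covariates[[nm]]
    stopifnot(!is.null(cv$levels), !is.null(cv$reference),
              cv$reference %in% cv$levels)
    for (mx in c("mix1", "mix2")) {
      p <- cv[[mx]]
      if (length(p) != length(cv$levels))
        stop("covariate '", nm, "': ", mx, " length does not match levels")
      if (abs(sum(p) - 1) > 1e-12)
        stop("covariate '", nm, "': ", mx, " does not sum to 1 (tolerance 1e-12)")
      if (any(p < 0)) stop("covariate '", nm, "': negative probability in ", mx)
    }
    expected <- c(expected,
                  paste0(nm, "=", setdiff(cv$levels, cv$reference)))
  }
  for (b in list(beta1 = beta1, beta2 = beta2)) {
    if (!identical(names(b), expected))
      stop("coefficient names/order must be: ", paste(expected, collapse = ", "))
  }
  structure(
    list(n = as.integer(n), p_group1 = p_group1, covariates = covariates,
         beta1 = beta1, beta2 = beta2, weight_shape = weight_shape,
         weight_scale = weight_scale, group2_weight_scale = group2_weight_scale,
         pregnancy_rate = pregnancy_rate, missing_bmi_rate = missing_bmi_rate,
         group_var = group_var, group_levels = group_levels,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Covariate schema implied by a synthetic configuration
#'
#' @param cfg a [synthetic_config()].
#' @return the matching [covariate_schema()].
#' @export
schema_from_config <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  covariate_schema(
    covariates = lapply(cfg$covariates, function(cv)
      list(levels = cv$levels, reference = cv$reference)),
    group_var = cfg$group_var, group_levels = cfg$group_levels
  )
}

# draw the covariate columns for n records from one group's mixes
draw_covariates <- function(cfg, n, mix_slot) {
  out <- list()
  for (nm in names(cfg$covariates)) {
    cv <- cfg$covariates[[nm]]
    out[[nm]] <- sample(cv$levels, n, replace = TRUE, prob = cv[[mix_slot]])
  }
  out
}

# linear predictor for given covariate columns under one beta vector
linear_predictor <- function(cfg, covcols, beta) {
  n <- length(covcols[[1]])
  eta <- rep(beta[["(Intercept)"]], n)
  for (nm in names(cfg$covariates)) {
    cv <- cfg$covariates[[nm]]
    contrib <- stats::setNames(rep(0, length(cv$levels)), cv$levels)
    nonref <- setdiff(cv$levels, cv$reference)
    contrib[nonref] <- beta[paste0(nm, "=", nonref)]
    eta <- eta + contrib[covcols[[nm]]]
  }
  unname(eta)
}

#' Generate a synthetic two-group survey sample
#'
#' Draws `n` records from the configured process: group membership
#' Bernoulli(`p_group1`); covariates independently per group from the
#' group's level mixes; outcome Bernoulli(inverse-logit of the group's
#' linear predictor); gamma sampling weights; pregnancy and missing-BMI
#' flags at the configured rates. The emitted table uses the CSV dialect
#' of [read_survey_csv()]: a BMI column consistent with the drawn
#' indicator (a synthetic placeholder, not an anthropometric model) so
#' the outcome-derivation and exclusion steps are exercised end to end.
#'
#' @param cfg a [synthetic_config()].
#' @return data.frame of raw records (columns: `id`, group variable,
#'   covariates, `bmi`, `pregnant`, `weight`).
#' @export
generate_sample <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  n <- cfg$n
  g1 <- stats::rbinom(n, 1L, cfg$p_group1) == 1L
  covcols <- lapply(names(cfg$covariates), function(nm) character(n))
  names(covcols) <- names(cfg$covariates)
  for (slot in c("mix1", "mix2")) {
    idx <- if (slot == "mix1") which(g1) else which(!g1)
    if (!length(idx)) next
    drawn <- draw_covariates(cfg, length(idx), slot)
    for (nm in names(drawn)) covcols[[nm]][idx] <- drawn[[nm]]
  }
  eta <- numeric(n)
  eta[g1] <- linear_predictor(cfg, lapply(covcols, `[`, which(g1)), cfg$beta1)
  eta[!g1] <- linear_predictor(cfg, lapply(covcols, `[`, which(!g1)), cfg$beta2)
  if (any(!is.finite(eta)))
    stop("non-finite linear predictor: coefficients too extreme")
  y <- stats::rbinom(n, 1L, stats::plogis(eta))

  # BMI consistent with the indicator: uniform within the WHO band either side
  bmi <- ifelse(y == 1L, stats::runif(n, 25, 42), stats::runif(n, 16.5, 24.99))
  if (cfg$missing_bmi_rate > 0)
    bmi[stats::runif(n) < cfg$missing_bmi_rate] <- NA_real_
  pregnant <- as.integer(stats::runif(n) < cfg$pregnancy_rate)

  w <- stats::rgamma(n, shape = cfg$weight_shape, scale = cfg$weight_scale)
  w[!g1] <- w[!g1] * cfg$group2_weight_scale

  out <- data.frame(
    id = sprintf("r%06d", seq_len(n)),
    group = ifelse(g1, cfg$group_levels[1], cfg$group_levels[2]),
    stringsAsFactors = FALSE
  )
  names(out)[2] <- cfg$group_var
  for (nm in names(covcols)) out[[nm]] <- covcols[[nm]]
  out$bmi <- bmi
  out$pregnant <- pregnant
  out$weight <- w
  out
}

# exact expected dummy-column means implied by the mixes (named like the
# encode_design_matrix layout, intercept included)
mix_dummy_means <- function(cfg, slot) {
  xb <- c(`(Intercept)` = 1)
  for (nm in names(cfg$covariates)) {
    cv <- cfg$covariates[[nm]]
    p <- stats::setNames(cv[[slot]], cv$levels)
    nonref <- setdiff(cv$levels, cv$reference)
    xb[paste0(nm, "=", nonref)] <- p[nonref]
  }
  xb
}

#' True decomposition components of a synthetic configuration
#'
#' Computes the ground-truth threefold decomposition of the group gap in
#' outcome probability implied by a [synthetic_config()], on two scales:
#'
#' * probability scale, via the counterfactual mean-prediction pairings
#'   \eqn{\bar P(\mathrm{mix}_g, \beta_h)}: the gap
#'   `D = P(mix1,b1) - P(mix2,b2)`; endowment
#'   `E = P(mix1,b2) - P(mix2,b2)`; coefficient
#'   `C = P(mix2,b1) - P(mix2,b2)` with its intercept-only share `B`
#'   isolated by a fifth pairing that swaps intercepts only; interaction
#'   `I = D - E - C` (residual-defined, so the identity is exact);
#' * linear-index scale, in closed form from the exact mean dummy
#'   vectors and coefficient differences (the classical threefold
#'   summation formulas), where the additive identity holds by algebra.
#'
#' The probability-scale pairings are evaluated by Monte Carlo over
#' covariate draws (`method = "montecarlo"`, chunked so memory stays
#' flat, with a standard error per component) or by exact enumeration of
#' the level combinations (`method = "exact"`, feasible because the
#' covariates are independent within group; standard errors are zero).
#'
#' @param cfg a [synthetic_config()].
#' @param oracle_n Monte-Carlo draws per mix (>= 1e6 recommended).
#' @param method `"montecarlo"` or `"exact"`.
#' @param se_tol optional cap: if any component's Monte-Carlo standard
#'   error exceeds it, an error asks for a larger `oracle_n`.
#' @return an object of class `synthetic_truth`: list with
#'   `mean_outcome_group1/2`, `D_true`, `E_true`, `C_true`, `I_true`,
#'   `B_true`, `linear` (closed-form linear-scale components),
#'   `oracle_n`, `oracle_se` (named per component).
#' @export
compute_truth <- function(cfg, oracle_n = 1e6,
                          method = c("montecarlo", "exact"), se_tol = Inf) {
  stopifnot(inherits(cfg, "synthetic_config"))
  method <- match.arg(method)

  # closed-form linear-index-scale components
  xb1 <- mix_dummy_means(cfg, "mix1")
  xb2 <- mix_dummy_means(cfg, "mix2")
  b1 <- cfg$beta1
  b2 <- cfg$beta2
  slope <- names(b1) != "(Intercept)"
  E_lin <- sum(b2[slope] * (xb1[slope] - xb2[slope]))
  B_lin <- unname(b1[["(Intercept)"]] - b2[["(Intercept)"]])
  C_lin <- sum(xb2[slope] * (b1[slope] - b2[slope])) + B_lin
  I_lin <- sum((xb1[slope] - xb2[slope]) * (b1[slope] - b2[slope]))
  linear <- c(D = E_lin + C_lin + I_lin, E = E_lin, C = C_lin,
              I = I_lin, B = B_lin)

  if (method == "exact") {
    grids <- lapply(names(cfg$covariates), function(nm) cfg$covariates[[nm]]$levels)
    names(grids) <- names(cfg$covariates)
    combos <- expand.grid(grids, stringsAsFactors = FALSE)
    covcols <- as.list(combos)
    prob_of <- function(slot) {
      p <- rep(1, nrow(combos))
      for (nm in names(cfg$covariates)) {
        cv <- cfg$covariates[[nm]]
        pl <- stats::setNames(cv[[slot]], cv$levels)
        p <- p * pl[covcols[[nm]]]
      }
      unname(p)
    }
    p1 <- prob_of("mix1"); p2 <- prob_of("mix2")
    eta_b1 <- linear_predictor(cfg, covcols, cfg$beta1)
    eta_b2 <- linear_predictor(cfg, covcols, cfg$beta2)
    swap <- eta_b2 - cfg$beta2[["(Intercept)"]] + cfg$beta1[["(Intercept)"]]
    P11 <- sum(p1 * stats::plogis(eta_b1))
    P12 <- sum(p1 * stats::plogis(eta_b2))
    P21 <- sum(p2 * stats::plogis(eta_b1))
    P22 <- sum(p2 * stats::plogis(eta_b2))
    P2s <- sum(p2 * stats::plogis(swap))
    se <- c(D = 0, E = 0, C = 0, I = 0, B = 0)
    oracle_n <- nrow(combos)
  } else {
    stopifnot(oracle_n >= 1)
    set.seed(substream_seed(cfg$seed, 97L))
    chunk <- 1e6
    acc <- stats::setNames(rep(0, 5), c("P11", "P12", "P21", "P22", "P2s"))
    ss <- stats::setNames(rep(0, 5), c("p11", "p12", "dC", "dB", "p22"))
    done <- 0
    while (done < oracle_n) {
      m <- min(chunk, oracle_n - done)
      cc1 <- draw_covariates(cfg, m, "mix1")
      e11 <- linear_predictor(cfg, cc1, cfg$beta1)
      e12 <- linear_predictor(cfg, cc1, cfg$beta2)
      p11 <- stats::plogis(e11); p12 <- stats::plogis(e12)
      cc2 <- draw_covariates(cfg, m, "mix2")
      e21 <- linear_predictor(cfg, cc2, cfg$beta1)
      e22 <- linear_predictor(cfg, cc2, cfg$beta2)
      es <- e22 - cfg$beta2[["(Intercept)"]] + cfg$beta1[["(Intercept)"]]
      p21 <- stats::plogis(e21); p22 <- stats::plogis(e22)
      p2s <- stats::plogis(es)
      acc <- acc + c(sum(p11), sum(p12), sum(p21), sum(p22), sum(p2s))
      ss <- ss + c(sum(p11^2), sum(p12^2),
                   sum((p21 - p22)^2), sum((p2s - p22)^2), sum(p22^2))
      done <- done + m
    }
    mu <- acc / oracle_n
    P11 <- mu[["P11"]]; P12 <- mu[["P12"]]; P21 <- mu[["P21"]]
    P22 <- mu[["P22"]]; P2s <- mu[["P2s"]]
    v <- function(sumsq, mean) pmax(sumsq / oracle_n - mean^2, 0) / oracle_n
    se11 <- sqrt(v(ss[["p11"]], P11))
    se12 <- sqrt(v(ss[["p12"]], P12))
    se22 <- sqrt(v(ss[["p22"]], P22))
    seC <- sqrt(v(ss[["dC"]], P21 - P22))   # paired on mix2 draws
    seB <- sqrt(v(ss[["dB"]], P2s - P22))
    seD <- sqrt(se11^2 + se22^2)
    seE <- sqrt(se12^2 + se22^2)
    se <- c(D = seD, E = seE, C = seC,
            I = sqrt(seD^2 + seE^2 + seC^2), B = seB)
    if (any(se > se_tol))
      stop("oracle standard error exceeds se_tol; increase oracle_n ",
           "(max se ", signif(max(se), 3), ")")
  }

  D <- P11 - P22
  E <- P12 - P22
  C <- P21 - P22
  structure(
    list(mean_outcome_group1 = P11, mean_outcome_group2 = P22,
         D_true = D, E_true = E, C_true = C, I_true = D - E - C,
         B_true = P2s - P22, linear = linear,
         oracle_n = oracle_n, oracle_se = se, method = method),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("True decomposition components (", x$method, " oracle, n = ",
      format(x$oracle_n, big.mark = ","), ")\n", sep = "")
  cat(sprintf("  group means: %.4f vs %.4f\n",
              x$mean_outcome_group1, x$mean_outcome_group2))
  comp <- c(D = x$D_true, E = x$E_true, C = x$C_true, I = x$I_true, B = x$B_true)
  for (nm in names(comp))
    cat(sprintf("  %s = %+.5f (MC se %.2g)\n", nm, comp[[nm]], x$oracle_se[[nm]]))
  cat("  linear-index scale: ",
      paste(sprintf("%s=%+.4f", names(x$linear), x$linear), collapse = " "), "\n")
  invisible(x)
}

#' Default synthetic configuration emulating the study conditions
#'
#' A ready-made [synthetic_config()] shaped like the 2018 Nigeria DHS
#' women's sample the package is designed around: 42.1% of records
#' urban; four covariates (wealth, education, media exposure,
#' contraceptive use) whose urban mixes are richer, more educated and
#' more media-exposed than the rural mixes; group-specific logit
#' coefficients producing an overweight/obesity prevalence near 0.35
#' urban vs 0.21 rural with an endowment-dominated gap; gamma(4, 0.25)
#' sampling weights (mean 1); 8% pregnancy and 3% missing-BMI rates.
#'
#' @param n sample size (default 20000).
#' @param seed integer seed.
#' @param pregnancy_rate,missing_bmi_rate override the default exclusion
#'   rates (set to 0 for estimator tests that want no exclusions).
#' @return a [synthetic_config()].
#' @export
default_synthetic_config <- function(n = 20000, seed = 1L,
                                     pregnancy_rate = 0.08,
                                     missing_bmi_rate = 0.03) {
  covs <- list(
    wealth = list(levels = c("poor", "middle", "rich"), reference = "poor",
                  mix1 = c(0.18, 0.22, 0.60), mix2 = c(0.48, 0.22, 0.30)),
    education = list(levels = c("none", "primary", "secondary", "tertiary"),
                     reference = "none",
                     mix1 = c(0.15, 0.15, 0.50, 0.20),
                     mix2 = c(0.42, 0.17, 0.35, 0.06)),
    media = list(levels = c("not_exposed", "exposed"), reference = "not_exposed",
                 mix1 = c(0.15, 0.85), mix2 = c(0.43, 0.57)),
    contraceptive = list(levels = c("none_user", "user"), reference = "none_user",
                         mix1 = c(0.12, 0.88), mix2 = c(0.20, 0.80))
  )
  nm <- c("(Intercept)", "wealth=middle", "wealth=rich",
          "education=primary", "education=secondary", "education=tertiary",
          "media=exposed", "contraceptive=user")
  beta1 <- stats::setNames(c(-2.0, 0.5, 1.0, 0.2, 0.3, 0.6, 0.25, 0.30), nm)
  beta2 <- stats::setNames(c(-2.1, 0.4, 0.9, 0.15, 0.25, 0.50, 0.20, 0.25), nm)
  synthetic_config(
    n = n, p_group1 = 0.421, covariates = covs, beta1 = beta1, beta2 = beta2,
    pregnancy_rate = pregnancy_rate, missing_bmi_rate = missing_bmi_rate,
    seed = seed
  )
}

#' Write a synthetic-truth report as JSON
#'
#' @param truth a `synthetic_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  jsonlite::write_json(
    list(mean_outcome_group1 = truth$mean_outcome_group1,
         mean_outcome_group2 = truth$mean_outcome_group2,
         D_true = truth$D_true, E_true = truth$E_true, C_true = truth$C_true,
         I_true = truth$I_true, B_true = truth$B_true,
         linear = as.list(truth$linear), oracle_n = truth$oracle_n,
         oracle_se = as.list(truth$oracle_se), method = truth$method),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
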