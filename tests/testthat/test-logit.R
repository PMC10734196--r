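make_binary_ds <- function(a, b, c, d, levels = c("urban", "rural")) {
  # 2x2: level1 (pos a, neg b), level2 (pos c, neg d); variable doubles
  # as group and covariate so single-covariate fits give the 2x2 OR
  rec <- data.frame(
    residence = rep(levels, c(a + b, c + d)),
    outcome = c(rep(c(1L, 0L), c(a, b)), rep(c(1L, 0L), c(c, d))),
    weight = 1, stringsAsFactors = FALSE)
  sch <- covariate_schema(
    covariates = list(residence = list(levels = levels,
                                       reference = levels[1])),
    group_var = "residence", group_levels = levels)
  apply_exclusions(validate_records(rec, sch), sch)
}

test_that("a balanced outcome-independent covariate gets a zero coefficient", {
  ds <- make_binary_ds(50, 50, 80, 80)
  fit <- fit_weighted_logit(ds)
  expect_true(fit$converged)
  expect_lt(abs(fit$coefficients[["residence=rural"]]), 1e-8)
})

test_that("the saturated 2x2 slope equals the closed-form log odds ratio", {
  ds <- make_binary_ds(37, 63, 22, 178)
  fit <- fit_weighted_logit(ds)
  expect_equal(fit$coefficients[["residence=rural"]],
               log((22 * 63) / (178 * 37)), tolerance = 1e-6)
  # intercept is the log odds at the reference level
  expect_equal(fit$coefficients[["(Intercept)"]], log(37 / 63),
               tolerance = 1e-6)
})

test_that("unit weights reproduce the unweighted ML fit; weight scale is irrelevant", {
  ds <- make_ds(small_cfg(n = 4000, seed = 21))
  fit <- fit_weighted_logit(ds, normalize_weights = FALSE)
  ref <- suppressWarnings(stats::glm(
    .outcome ~ wealth + media, family = binomial(),
    data = transform(ds$records,
                     wealth = relevel(wealth, "poor"),
                     media = relevel(media, "not_exposed")),
    weights = ds$records$.weight))
  expect_equal(unname(fit$coefficients), unname(coef(ref)),
               tolerance = 1e-8)

  ds7 <- ds
  ds7$records$.weight <- ds7$records$.weight * 7
  fit7 <- fit_weighted_logit(ds7, normalize_weights = FALSE)
  expect_equal(fit7$coefficients, fit$coefficients, tolerance = 1e-8)
  # with normalization the covariance is weight-scale-free too
  v1 <- fit_weighted_logit(ds, normalize_weights = TRUE)$vcov
  v7 <- fit_weighted_logit(ds7, normalize_weights = TRUE)$vcov
  expect_equal(v1, v7, tolerance = 1e-8)
})

test_that("swapping the reference level rescales odds ratios consistently", {
  cfg <- small_cfg(n = 4000, seed = 22)
  ds <- make_ds(cfg)
  or1 <- odds_ratio_table(fit_weighted_logit(ds, covariates = "wealth"))

  sch2 <- schema_from_config(cfg)
  sch2$covariates$wealth$reference <- "middle"
  ds2 <- apply_exclusions(validate_records(generate_sample(cfg), sch2), sch2)
  or2 <- odds_ratio_table(fit_weighted_logit(ds2, covariates = "wealth"))

  g1 <- function(t, l) t$OR[t$level == l]
  expect_equal(g1(or2, "rich"), g1(or1, "rich") / g1(or1, "middle"),
               tolerance = 1e-6)
  expect_equal(g1(or2, "poor"), 1 / g1(or1, "middle"), tolerance = 1e-6)
})

test_that("odds-ratio tables carry references, ordered Wald intervals and p-values", {
  ds <- make_ds(small_cfg(n = 4000, seed = 23))
  fit <- fit_weighted_logit(ds)
  tab <- odds_ratio_table(fit)
  expect_true(all(tab$OR[tab$is_reference] == 1))
  expect_true(all(is.na(tab$CI_low[tab$is_reference])))
  nr <- !tab$is_reference
  expect_true(all(tab$CI_low[nr] <= tab$OR[nr] & tab$OR[nr] <= tab$CI_high[nr]))
  expect_true(all(tab$p_value[nr] >= 0 & tab$p_value[nr] <= 1))
  # OR = exp(beta) on matching rows
  expect_equal(tab$OR[nr],
               unname(exp(fit$coefficients[-1])), tolerance = 1e-12)

  # the unadjusted sweep yields one block per schema covariate
  sweep <- unadjusted_or_sweep(ds)
  expect_equal(unique(sweep$covariate), c("wealth", "media"))
  expect_equal(sum(sweep$is_reference), 2L)
})

test_that("rank deficiency and separation are detected, not silently fitted", {
  sch <- covariate_schema(
    covariates = list(
      a = list(levels = c("x", "y"), reference = "x"),
      b = list(levels = c("x", "y"), reference = "x")),
    group_var = "residence", group_levels = c("urban", "rural"))
  rec <- data.frame(
    residence = rep(c("urban", "rural"), 50),
    a = rep(c("x", "y"), each = 50),
    b = rep(c("x", "y"), each = 50),  # duplicate of a
    outcome = rep(c(0L, 1L), 50), weight = 1, stringsAsFactors = FALSE)
  ds <- apply_exclusions(validate_records(rec, sch), sch)
  expect_error(fit_weighted_logit(ds), "collinear.*b=y")

  # perfectly separated outcome
  sch1 <- covariate_schema(
    covariates = list(a = list(levels = c("x", "y"), reference = "x")),
    group_var = "residence", group_levels = c("urban", "rural"))
  rec1 <- data.frame(
    residence = rep(c("urban", "rural"), 40),
    a = rep(c("x", "y"), each = 40),
    outcome = rep(c(0L, 1L), each = 40), weight = 1,
    stringsAsFactors = FALSE)
  ds1 <- apply_exclusions(validate_records(rec1, sch1), sch1)
  expect_error(suppressWarnings(fit_weighted_logit(ds1)), "quasi-separation")
})

test_that("group-specific fits recover the generating coefficients", {
  cfg <- small_cfg(n = 30000, seed = 24)
  ds <- make_ds(cfg)
  for (g in 1:2) {
    fit <- fit_weighted_logit(ds, subset = cfg$group_levels[g])
    truth <- if (g == 1) cfg$beta1 else cfg$beta2
    se <- sqrt(diag(fit$vcov))
    expect_true(all(abs(fit$coefficients - truth) < 4 * se))
  }
})
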