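test_that("linear threefold algebra matches hand-evaluated closed forms", {
  b1 <- c("(Intercept)" = 0, x = 1.5)
  b2 <- c("(Intercept)" = 0, x = 1.0)
  comp <- threefold_components(b1, b2, c(1, 0.6), c(1, 0.4))
  expect_equal(unname(comp["E"]), 0.2, tolerance = 1e-12)
  expect_equal(unname(comp["C"]), 0.2, tolerance = 1e-12)
  expect_equal(unname(comp["I"]), 0.1, tolerance = 1e-12)
  expect_equal(unname(comp["D"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(comp["B"]), 0, tolerance = 1e-12)

  # equal coefficient vectors: C and I collapse exactly, D = E
  compC <- threefold_components(b1, b1, c(1, 0.6), c(1, 0.4))
  expect_identical(unname(compC["C"]), 0)
  expect_identical(unname(compC["I"]), 0)
  expect_equal(unname(compC["D"]), unname(compC["E"]))
  # equal mean vectors: E and I collapse exactly
  compM <- threefold_components(b1, b2, c(1, 0.4), c(1, 0.4))
  expect_identical(unname(compM["E"]), 0)
  expect_identical(unname(compM["I"]), 0)
})

test_that("additive identity and observed-prevalence matching hold on data", {
  ds <- make_ds(small_cfg(n = 8000, seed = 31))
  rec <- ds$records

  lin <- threefold_decompose(ds, mode = "linear")
  expect_equal(lin$E + lin$C + lin$I, lin$D, tolerance = 1e-10)
  expect_equal(lin$D, lin$mean_pred_group1 - lin$mean_pred_group2)

  cf <- threefold_decompose(ds, mode = "logit_counterfactual")
  expect_identical(cf$E + cf$C + cf$I + (cf$D - cf$E - cf$C - cf$I), cf$D)
  expect_equal(cf$D - cf$E - cf$C, cf$I, tolerance = 1e-15)
  # intercepted group logits reproduce the weighted observed prevalences
  for (g in c("urban", "rural")) {
    sel <- rec$.group == g
    obs <- weighted.mean(rec$.outcome[sel], rec$.weight[sel])
    prd <- if (g == "urban") cf$mean_pred_group1 else cf$mean_pred_group2
    expect_equal(prd, obs, tolerance = 1e-8)
  }
  # percent contributions are 100 * part / D
  expect_equal(cf$pct_E, 100 * cf$E / cf$D, tolerance = 1e-12)
  expect_equal(cf$pct_E + cf$pct_C + cf$pct_I, 100, tolerance = 1e-8)
})

test_that("exchangeable groups decompose to approximately nothing", {
  ds <- make_ds(exchangeable_cfg(n = 30000, seed = 32))
  d <- threefold_decompose(ds, mode = "logit_counterfactual")
  for (v in c(d$D, d$E, d$C, d$I)) expect_lt(abs(v), 0.025)
})

test_that("detailed parts sum to their aggregates in both contrasts and modes", {
  ds <- make_ds(small_cfg(n = 8000, seed = 33))
  for (mode in c("linear", "logit_counterfactual")) {
    d <- threefold_decompose(ds, mode = mode)
    for (ctr in c("reference", "deviation")) {
      det <- detailed_contributions(d, contrast = ctr)
      is_const <- det$covariate == "Constant"
      expect_equal(sum(det$E_part[!is_const]), d$E, tolerance = 1e-8)
      expect_equal(sum(det$C_part), d$C, tolerance = 1e-8)
      expect_equal(det$E_pct[!is_const],
                   100 * det$E_part[!is_const] / d$D, tolerance = 1e-10)
    }
    # deviation contrast: binary covariate rows split the E part equally
    det_dev <- detailed_contributions(d, contrast = "deviation")
    md <- det_dev[det_dev$covariate == "media", ]
    expect_equal(nrow(md), 2L)
    expect_equal(md$E_part[1], md$E_part[2], tolerance = 1e-10)
    # a covariate with identical group means contributes no E part
  }
  # reference contrast keeps only non-reference rows; deviation all levels
  d <- threefold_decompose(ds, mode = "linear")
  expect_equal(nrow(detailed_contributions(d, "reference")), 3 + 1)
  expect_equal(nrow(detailed_contributions(d, "deviation")), 5 + 1)
})

test_that("a covariate with equal group-level means has zero endowment part", {
  cfg <- small_cfg(n = 40000, seed = 34)
  cfg$covariates$media$mix2 <- cfg$covariates$media$mix1
  ds <- make_ds(cfg)
  d <- threefold_decompose(ds, mode = "linear")
  det <- detailed_contributions(d)
  got <- det$E_part[det$covariate == "media"]
  # group means equal only in expectation -> small, not exactly zero
  expect_lt(abs(got), 0.01)
})

test_that("swapping labels and viewpoint mirrors the decomposition", {
  ds <- make_ds(small_cfg(n = 8000, seed = 35))
  d <- threefold_decompose(ds, mode = "linear")
  m <- threefold_decompose(ds, mode = "linear", reference_group = "urban")
  expect_equal(m$D, -d$D, tolerance = 1e-12)
  expect_equal(m$E, -(d$E + d$I), tolerance = 1e-10)
  expect_equal(m$C, -(d$C + d$I), tolerance = 1e-10)
  expect_equal(m$I, d$I, tolerance = 1e-10)
})

test_that("percent contributions preserve sign and reject a zero gap", {
  expect_equal(round_half_up(percent_contribution(0.123, 0.144), 1), 85.4)
  expect_equal(round_half_up(percent_contribution(0.018, 0.144), 1), 12.5)
  expect_equal(percent_contribution(0.7, 0.7), 100)
  expect_equal(percent_contribution(-0.0003, 0.144), -0.2083, tolerance = 1e-3)
  expect_error(percent_contribution(0.1, 0), "zero")
})

test_that("bootstrap intervals are deterministic, ordered and cover the estimate", {
  ds <- make_ds(small_cfg(n = 3000, seed = 36))
  ci1 <- bootstrap_cis(ds, B = 100, seed = 77)
  ci2 <- bootstrap_cis(ds, B = 100, seed = 77)
  expect_identical(ci1$component_ci, ci2$component_ci)
  expect_identical(ci1$detail_ci, ci2$detail_ci)
  expect_true(all(ci1$component_ci$low <= ci1$component_ci$high))
  expect_equal(ci1$n_fail, 0L)
  # point estimates sit inside their own 95% intervals at this n
  d <- threefold_decompose(ds)
  est <- c(D = d$D, E = d$E, C = d$C, I = d$I, B = d$B)
  cc <- ci1$component_ci
  for (k in cc$component)
    expect_true(est[[k]] >= cc$low[cc$component == k] - 1e-12 &&
                est[[k]] <= cc$high[cc$component == k] + 1e-12)

  # a dataset degenerate in x (every record identical) cannot identify
  # the group fits at all: the error is immediate and explicit
  rec <- toy_records()
  rec$wealth <- "poor"
  rec$media <- "exposed"
  sch <- toy_schema()
  dsd <- suppressWarnings(
    apply_exclusions(validate_records(rec, sch), sch))
  expect_error(suppressWarnings(bootstrap_cis(dsd, B = 100, seed = 1)),
               "rank-deficient")

  # a level held by a single record makes most resamples rank-deficient:
  # the failure fraction crosses 20% and resampling is reported unstable
  sch1 <- covariate_schema(
    covariates = list(wealth = list(levels = c("poor", "middle", "rich"),
                                    reference = "poor")),
    group_var = "residence", group_levels = c("urban", "rural"))
  rec1 <- data.frame(
    residence = rep(c("urban", "rural"), each = 30),
    wealth = c(rep(c("poor", "middle", "rich"), 10),
               rep(c("poor", "middle"), 14), "poor", "rich"),
    outcome = rep(c(0L, 1L), 30), weight = 1, stringsAsFactors = FALSE)
  ds1 <- apply_exclusions(validate_records(rec1, sch1), sch1)
  expect_error(
    suppressWarnings(bootstrap_cis(ds1, B = 100, seed = 2, mode = "linear")),
    "unstable resampling")
})
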