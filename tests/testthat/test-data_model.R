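test_that("BMI indicator codes the overweight threshold and routes missingness", {
  expect_identical(derive_outcome(c(25, 24.99, 17, 31.4)), c(1L, 0L, 0L, 1L))
  expect_identical(derive_outcome(c(NA, NaN, Inf * 0)), rep(NA_integer_, 3))
  expect_error(derive_outcome(-3), "non-positive")

  # monotone non-decreasing in BMI
  grid <- sort(c(runif(200, 12, 45), 24.999, 25, 25.001))
  expect_true(all(diff(derive_outcome(grid)) >= 0))
})

test_that("exclusion rules remove pregnant and missing-BMI records with audited counts", {
  sch <- toy_schema()
  rec <- toy_records()[c(1, 2, 3, 11, 12), ]
  rec$pregnant[2] <- 1L
  rec$bmi[4] <- NA
  ds <- apply_exclusions(validate_records(rec, sch), sch)
  expect_equal(nrow(ds$records), 3L)
  expect_equal(ds$n_excluded_pregnant, 1L)
  expect_equal(ds$n_excluded_missing, 1L)
  expect_equal(nrow(ds$records),
               ds$n_raw - ds$n_excluded_pregnant - ds$n_excluded_missing -
                 ds$n_excluded_covariate)
  # order of survivors preserved
  expect_identical(ds$records$.id, c("p1", "p3", "p12"))

  # identity case: nothing flagged, nothing lost
  ds0 <- toy_dataset()
  expect_equal(ds0$n_excluded_pregnant, 0L)
  expect_equal(ds0$n_excluded_missing, 0L)
  expect_equal(nrow(ds0$records), 13L)

  # counts are permutation-invariant
  set.seed(42)
  rec_shuf <- rec[sample.int(nrow(rec)), ]
  ds_shuf <- apply_exclusions(validate_records(rec_shuf, sch), sch)
  expect_equal(ds_shuf$n_excluded_pregnant, ds$n_excluded_pregnant)
  expect_equal(ds_shuf$n_excluded_missing, ds$n_excluded_missing)

  # everything excluded -> empty analysis set
  rec_all <- toy_records()
  rec_all$pregnant <- 1L
  expect_error(apply_exclusions(validate_records(rec_all, sch), sch),
               "empty analysis set")

  # only one group surviving -> degenerate grouping
  rec_one <- toy_records()
  rec_one$pregnant[rec_one$residence == "rural"] <- 1L
  expect_error(apply_exclusions(validate_records(rec_one, sch), sch),
               "degenerate grouping")
})

test_that("design matrix is k-1 dummy coding with an exact decoding round-trip", {
  ds <- toy_dataset()
  X <- encode_design_matrix(ds)
  # 1 intercept + (3-1) + (2-1) columns on the 13-record fixture
  expect_equal(ncol(X), 4L)
  expect_identical(colnames(X),
                   c("(Intercept)", "wealth=middle", "wealth=rich",
                     "media=exposed"))
  # column sums equal level tallies
  expect_equal(unname(colSums(X)),
               c(13, sum(toy_records()$wealth == "middle"),
                 sum(toy_records()$wealth == "rich"),
                 sum(toy_records()$media == "exposed")))
  # a record at the reference level of everything is (1, 0, 0, 0)
  ref_row <- which(ds$records$wealth == "poor" &
                     ds$records$media == "not_exposed")[1]
  expect_equal(unname(X[ref_row, ]), c(1, 0, 0, 0))
  # decoding reproduces every record's labels exactly
  for (i in seq_len(nrow(X))) {
    lab <- decode_design_row(X[i, ], X)
    expect_identical(unname(lab["wealth"]), as.character(ds$records$wealth[i]))
    expect_identical(unname(lab["media"]), as.character(ds$records$media[i]))
  }
  # a declared level absent from the data keeps an all-zero column
  rec <- toy_records()
  rec$wealth[rec$wealth == "rich"] <- "poor"
  dsr <- apply_exclusions(validate_records(rec, toy_schema()), toy_schema())
  expect_warning(Xr <- encode_design_matrix(dsr), "all-zero")
  expect_true("wealth=rich" %in% colnames(Xr))
  expect_equal(sum(Xr[, "wealth=rich"]), 0)
})

test_that("validation rejects conflicts and undeclared labels; CSV round-trips", {
  sch <- toy_schema()
  rec <- toy_records()
  rec$outcome <- derive_outcome(rec$bmi)
  rec$outcome[3] <- 1L - rec$outcome[3]
  expect_error(validate_records(rec, sch), "contradicting BMI")

  rec2 <- toy_records()
  rec2$wealth[1] <- "affluent"
  expect_error(validate_records(rec2, sch), "undeclared level")

  rec3 <- toy_records()
  rec3$weight[2] <- -1
  expect_error(validate_records(rec3, sch), "non-positive sampling weight")

  ds <- toy_dataset()
  f <- tempfile(fileext = ".csv")
  write_analysis_csv(ds, f)
  ds2 <- apply_exclusions(read_survey_csv(f, sch), sch)
  expect_equal(ds2$records$.outcome, ds$records$.outcome)
  expect_equal(as.character(ds2$records$wealth), as.character(ds$records$wealth))
  expect_equal(ds2$records$.weight, ds$records$.weight)
  unlink(f)
})

test_that("synthetic batches respect the configured exclusion rates", {
  cfg <- small_cfg(n = 20000, seed = 11,
                   pregnancy_rate = 0.1, missing_bmi_rate = 0.05)
  smp <- generate_sample(cfg)
  sch <- schema_from_config(cfg)
  ds <- apply_exclusions(validate_records(smp, sch), sch)
  # retained fraction ~ 0.9 * (1 - rate among non-pregnant)
  expect_equal(ds$n_excluded_pregnant, sum(smp$pregnant == 1L))
  expect_equal(ds$n_excluded_missing,
               sum(is.na(smp$bmi) & smp$pregnant == 0L))
  expect_equal(nrow(ds$records) / cfg$n, 0.9 * 0.95, tolerance = 0.02)
})
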