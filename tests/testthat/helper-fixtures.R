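# Shared fixtures: all built in code, no files.

toy_schema <- function() {
  covariate_schema(
    covariates = list(
      wealth = list(levels = c("poor", "middle", "rich"), reference = "poor"),
      media = list(levels = c("not_exposed", "exposed"),
                   reference = "not_exposed")
    ),
    group_var = "residence", group_levels = c("urban", "rural")
  )
}

# 13 hand-built records over the toy schema (2 covariates: 3 + 2 levels)
toy_records <- function() {
  data.frame(
    id = paste0("p", 1:13),
    residence = c(rep("urban", 6), rep("rural", 7)),
    wealth = c("poor", "middle", "rich", "rich", "rich", "middle",
               "poor", "poor", "poor", "middle", "rich", "poor", "poor"),
    media = c("exposed", "exposed", "exposed", "not_exposed", "exposed",
              "exposed", "not_exposed", "not_exposed", "exposed",
              "not_exposed", "exposed", "not_exposed", "not_exposed"),
    bmi = c(27, 31, 26, 24, 29, 23, 18, 22, 26, 21, 28, 19, 24),
    pregnant = 0L,
    weight = 1,
    stringsAsFactors = FALSE
  )
}

toy_dataset <- function() {
  sch <- toy_schema()
  apply_exclusions(validate_records(toy_records(), sch), sch)
}

# compact 2-covariate generating process used for property and
# coverage checks (no pregnancy / missing-BMI noise)
small_cfg <- function(n = 5000, seed = 1L, ...) {
  covs <- list(
    wealth = list(levels = c("poor", "middle", "rich"), reference = "poor",
                  mix1 = c(0.2, 0.3, 0.5), mix2 = c(0.5, 0.3, 0.2)),
    media = list(levels = c("not_exposed", "exposed"),
                 reference = "not_exposed",
                 mix1 = c(0.2, 0.8), mix2 = c(0.5, 0.5))
  )
  nm <- c("(Intercept)", "wealth=middle", "wealth=rich", "media=exposed")
  synthetic_config(
    n = n, p_group1 = 0.45, covariates = covs,
    beta1 = stats::setNames(c(-1.2, 0.4, 0.9, 0.3), nm),
    beta2 = stats::setNames(c(-1.4, 0.3, 0.7, 0.2), nm),
    seed = seed, ...
  )
}

# same mixes and coefficients in both groups: exchangeable by design
exchangeable_cfg <- function(n = 20000, seed = 1L) {
  cfg <- small_cfg(n = n, seed = seed)
  cfg$covariates$wealth$mix2 <- cfg$covariates$wealth$mix1
  cfg$covariates$media$mix2 <- cfg$covariates$media$mix1
  cfg$beta2 <- cfg$beta1
  cfg
}

make_ds <- function(cfg) {
  sch <- schema_from_config(cfg)
  apply_exclusions(validate_records(generate_sample(cfg), sch), sch)
}

# expand per-level (n, n_positive) aggregates into unit-weight records
# where one variable is both the grouping variable and a covariate
expand_binary_counts <- function(var, levels, n, n_pos) {
  rec <- data.frame(
    g = rep(levels, times = n),
    outcome = unlist(mapply(function(tot, pos) rep(c(1L, 0L), c(pos, tot - pos)),
                            n, n_pos, SIMPLIFY = FALSE)),
    weight = 1,
    stringsAsFactors = FALSE
  )
  names(rec)[1] <- var
  rec
}
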