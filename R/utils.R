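#' Round half away from zero
#'
#' Table-rendering rounding convention: halves round away from zero
#' (so 24.25 -> 24.3 and -24.25 -> -24.3), unlike [round()]'s
#' round-half-to-even. Underlying values are always stored at full
#' precision; this is applied only when rendering.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Format a p-value for table output
#'
#' Values below `floor` render as `"< 0.001"`; otherwise three decimals.
#'
#' @param p numeric vector of p-values.
#' @param floor smallest p-value printed exactly.
#' @return character vector.
#' @export
format_p <- function(p, floor = 0.001) {
  out <- sprintf("%.3f", p)
  out[!is.na(p) & p < floor] <- paste("<", format(floor))
  out[is.na(p)] <- NA_character_
  out
}

#' Derive a reproducible sub-stream seed
#'
#' Fans a single top-level seed out to stage-specific seeds so one
#' integer reproduces a whole pipeline run. Result is always a positive
#' integer below 2^31 - 1.
#'
#' @param seed integer master seed.
#' @param k integer stream index (stage number).
#' @return a single integer seed.
#' @export
substream_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647
  s <- (abs(seed) %% m) * 48271 %% m
  as.integer((s + (k %% m) * 7919) %% m + 1)
}

# significance stars at the conventional 0.1 / 0.05 / 0.01 thresholds
p_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.01, "***", ifelse(p < 0.05, "**", ifelse(p < 0.1, "*", ""))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# weighted mean that errors on zero total weight
wmean <- function(x, w) {
  tw <- sum(w)
  if (tw <= 0) stop("zero total weight")
  sum(x * w) / tw
}
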