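# Internal helpers shared across modules.

#' Round a percentage to two decimals
#'
#' Percentages throughout the package are reported half-even rounded to two
#' decimals (the convention of the published network tables); raw values are
#' kept internally wherever downstream arithmetic needs them.
#'
#' @param x numeric vector.
#' @return `x` rounded to 2 decimal places.
#' @export
pct2 <- function(x) round(x, 2)

#' Percentage of a count over a total, 2-decimal rounded
#'
#' @param count numerator count.
#' @param total denominator count; must be positive.
#' @return `100 * count / total` rounded to two decimals.
#' @export
pct_of <- function(count, total) {
  stopifnot(is.numeric(count), is.numeric(total), total > 0)
  pct2(100 * count / total)
}

# Derive a per-replicate child seed from a base seed; stays below 2^31-1 so
# it is always a valid R integer seed.
derive_seed <- function(base_seed, i) {
  as.integer((as.double(base_seed) * 48271 + i * 10007) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Split a semicolon-separated field into a sorted character set ("" -> empty).
split_set <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  sort(unique(trimws(strsplit(x, ";", fixed = TRUE)[[1]])))
}

join_set <- function(x) paste(sort(unique(x)), collapse = ";")
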