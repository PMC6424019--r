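#' Round half up
#'
#' Rounds to `digits` decimal places with ties away from zero, matching the
#' conventional formatting of published measurement tables (base R's
#' `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 0).
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(2.5)       # 3
#' round_half_up(0.605, 2)  # 0.61
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Deterministic per-object substream: derive a 32-bit seed from a global seed
# and an object counter so adding object k+1 never perturbs objects 1..k.
substream_seed <- function(seed, counter) {
  s <- (as.double(seed) %% 2147483647) * 69621 + as.double(counter) * 16807
  as.integer(s %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
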