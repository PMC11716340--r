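# Shared internal helpers: reporting-grade rounding and a keyed RNG stream.

#' Round half-up
#'
#' Rounds to `digits` decimals with ties going away from zero, the convention
#' used for every percentage printed in reports. Base R's `round()` uses
#' round-half-even, which would print 0.05 -> 0.0; reports here expect 0.1.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 1).
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Stable 31-bit string hash (polynomial rolling hash in double arithmetic).
# Used only to derive per-key sub-seeds; not cryptographic.
.hash_string <- function(s) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 2147483647
  h
}

# Sub-seed for the keyed simulation stream. Keyed by (seed, gene, dose) so
# that subsetting or reordering genes never reshuffles another gene's draws.
.sub_seed <- function(seed, gene_id, dose) {
  h <- .hash_string(gene_id)
  (seed + h * 1299721 + round(dose * 1000) * 7919) %% 2147483647
}

# Evaluate `expr` under a local RNG seed, restoring the global stream after.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# stop() with a consistent prefix carrying a row locator when available.
.fail <- function(..., row = NULL) {
  msg <- paste0(...)
  if (!is.null(row)) msg <- sprintf("%s (row %s)", msg, paste(row, collapse = ", "))
  stop(msg, call. = FALSE)
}
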