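# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific seed from a global seed
#'
#' Each pipeline stage draws its own seed so that stages can be re-run in
#' isolation and still reproduce the full-pipeline behaviour. The rule is a
#' fixed affine map modulo the largest 32-bit prime, keeping the result a
#' valid R integer seed.
#'
#' @param seed Integer global seed.
#' @param stage Integer stage index (>= 0).
#' @return An integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(stage))
  as.integer((abs(seed) * 131L + stage * 7919) %% 2147483629)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Assert a scalar count (non-negative integer-valued numeric)
check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x))
    stopf("'%s' must be a single integer >= %d", name, min)
  as.integer(x)
}

check_scalar <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x > max)
    stopf("'%s' must be a single number in [%s, %s]", name, min, max)
  as.numeric(x)
}
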