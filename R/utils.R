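# Internal helpers shared across the package.

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the RNG with `seed`, runs `expr`, and restores the caller's RNG
#' state afterwards so library code never clobbers user-level randomness.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed %% 2147483647L))
  }
  force(expr)
}

#' Derive a bounded child seed from a master seed and counters
#'
#' Deterministic counter scheme so any single unit of work (a trial, a fold
#' assignment) is regenerable in isolation. Always returns a positive
#' integer below 2^31 - 1.
#' @noRd
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master) %% 2147483647
  for (k in idx) {
    s <- (s * 48271 + as.double(k)) %% 2147483647
  }
  as.integer(s) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
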