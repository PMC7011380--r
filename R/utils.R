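# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded module calls never disturb the
#' caller's RNG stream.
#' @noRd
local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had_seed) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

#' Derive a stage-specific sub-seed from a global seed
#'
#' Multiplicative-counter scheme: adding a stage never perturbs the streams of
#' earlier stages. Result always lies in `[1, 2^31 - 2]`.
#'
#' @param seed Integer global seed.
#' @param stage Integer stage counter (0, 1, 2, ...).
#' @return A positive integer seed.
#' @export
#' @examples
#' subseed(1L, 0L)
#' subseed(1L, 1L)
subseed <- function(seed, stage) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(stage) * 16807
  as.integer(s %% 2147483646) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Numerically safe sigmoid.
sigmoid <- function(x) 1 / (1 + exp(-x))
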