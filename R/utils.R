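# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local RNG seed
#'
#' Runs `code` with the global random-number state set from `seed`, then
#' restores whatever state existed before the call, so generators are pure
#' functions of their (config, seed) arguments with no hidden global state.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# stop() without the call, with sprintf-style formatting
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# check a single-string argument
is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
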