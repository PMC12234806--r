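# Internal helpers shared across modules.

#' Evaluate an expression under a local, seeded RNG state
#'
#' All stochastic operations in the package route their randomness through
#' this helper so that a single integer seed fully determines the result and
#' the caller's global RNG state is left untouched.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("config error: 'seed' must be a single integer", call. = FALSE)
  }
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
  expr
}

# Derive a stream-specific child seed from a master seed, keeping the result
# inside the signed 32-bit integer range.
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1103L + stream * 12347L) %% 2147483647)
}

stop_config <- function(fmt, ...) {
  stop(sprintf(paste0("config error: ", fmt), ...), call. = FALSE)
}

stop_input <- function(fmt, ...) {
  stop(sprintf(paste0("input error: ", fmt), ...), call. = FALSE)
}

stop_domain <- function(fmt, ...) {
  stop(sprintf(paste0("domain error: ", fmt), ...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
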