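# internal helpers shared across modules

#' Evaluate an expression under a local, restorable RNG state
#'
#' Used by every stochastic entry point so that a supplied `seed` makes the
#' call bit-reproducible without clobbering the caller's RNG stream.
#'
#' @param seed Integer seed or `NULL` (use the current stream).
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
withSeed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed < 0) {
    stop("'seed' must be a single non-negative number", call. = FALSE)
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
  set.seed(as.integer(seed %% .Machine$integer.max))
  code
}

# derive a bounded child seed from a master seed and a stream label, so that
# one scenario seed spawns independent per-module substreams
childSeed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (as.integer(seed) * 7919L + as.integer(h %% 104729)) %% 2147483629L
}

stopifnotScalar <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    stop(sprintf("'%s' must be a single number in [%s, %s]", name,
                 format(min), format(max)), call. = FALSE)
  }
  invisible(x)
}

# binomial draw that degrades to the expectation in deterministic mode
drawBinom <- function(n, p, deterministic) {
  p <- min(max(p, 0), 1)
  if (deterministic) return(n * p)
  if (n <= 0) return(0)
  stats::rbinom(1L, as.integer(round(n)), p)
}
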