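# internal helpers

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("'%s' must be a single finite number", name)
  }
  if (x < lower || x > upper) {
    stopf("'%s' must be in [%s, %s], got %s", name, lower, upper, x)
  }
  invisible(x)
}

assert_count <- function(x, name, lower = 0) {
  if (!is_count(x) || x < lower) {
    stopf("'%s' must be an integer >= %d", name, lower)
  }
  invisible(as.integer(x))
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so the
#' generators never leak hidden global random state.
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# derive a stream seed from a base seed, staying inside 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 97 + offset) %% 2147483647)
}
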