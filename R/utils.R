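#' Derive a child seed from a master seed
#'
#' All randomness in the package flows from a single master seed through named
#' substreams, so that every stage (simulation, each resampling repeat, each
#' forest iteration) is independently reproducible.  Keys are folded into the
#' master seed with a polynomial string hash modulo 2^31 - 1, keeping results
#' inside R's 32-bit integer range.
#'
#' @param master integer master seed.
#' @param ... further keys (strings or integers) naming the substream,
#'   e.g. `derive_seed(seed, "plsda", repeat_index)`.
#' @return a positive integer seed.
#' @export
derive_seed <- function(master, ...) {
  keys <- list(...)
  m <- 2147483647            # 2^31 - 1, Mersenne prime
  h <- as.numeric(master) %% m
  for (k in keys) {
    chars <- utf8ToInt(paste0("|", as.character(k)))
    for (ch in chars) h <- (h * 131 + ch) %% m
  }
  as.integer(h %% (m - 1L) + 1L)
}

#' Evaluate an expression with a local RNG state
#'
#' Sets the seed, evaluates, and restores the caller's RNG state, so seeded
#' internals never disturb the user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# stop() with a consistent prefix; cheap sprintf-style wrapper
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# is x a single finite number?
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
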