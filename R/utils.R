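# Internal helpers shared across the package.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global random number generator seeded at `seed`, then
#' restores the caller's RNG state, so seeded package functions do not disturb
#' a user's simulation stream. With `seed = NULL` the expression runs on the
#' current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single number or NULL", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Frequency assigned to an allele absent from (or removed from) a reference
# sample of n typed individuals: 1/(2n + 1).
.rare_freq <- function(n_typed) 1 / (2 * n_typed + 1)

.stop_arg <- function(...) stop(..., call. = FALSE)

# collapse a character vector for messages
.quote_join <- function(x) paste(sQuote(x, q = FALSE), collapse = ", ")
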