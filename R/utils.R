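# Condition helpers: every user-facing failure carries one of three classes so
# callers (and the command-line wrapper) can map them to exit codes.
stop_config <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "nodewalk_config_error")
}

stop_data <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "nodewalk_data_error")
}

stop_numeric <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "nodewalk_numeric_error")
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. With seed = NULL the global stream is used.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_config("`seed` must be a single finite integer.")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(expr)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Reverse cumulative sums down the rows of a matrix (risk-set accumulation).
rev_cumsum_matrix <- function(m) {
  n <- nrow(m)
  if (n == 0L) return(m)
  out <- apply(m[n:1, , drop = FALSE], 2L, cumsum)
  out <- matrix(out, nrow = n)
  out[n:1, , drop = FALSE]
}
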