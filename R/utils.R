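# Internal helpers: deterministic per-operation RNG streams and argument checks.

# Derive a 31-bit seed from (seed, operation name) so that every generator
# draws from its own named stream: adding a new stage to a pipeline never
# perturbs the randomness consumed by existing stages.
stream_seed <- function(seed, op) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  codes <- utf8ToInt(op)
  h <- (abs(seed) %% 2147483647)
  for (k in seq_along(codes)) {
    h <- (h * 31 + codes[k] * k) %% 2147483647
  }
  as.integer((h + 1) %% 2147483647)
}

# Evaluate `expr` under the named stream without disturbing the caller's RNG.
with_stream <- function(seed, op, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, op))
  force(expr)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, allow_null = FALSE) {
  if (is.null(x) && allow_null) return(invisible(x))
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    rlang::abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_lower && x <= lower) {
    rlang::abort(sprintf("`%s` must be > %s (got %s).", name, lower, x))
  }
  if (!strict_lower && x < lower) {
    rlang::abort(sprintf("`%s` must be >= %s (got %s).", name, lower, x))
  }
  if (x > upper) {
    rlang::abort(sprintf("`%s` must be <= %s (got %s).", name, upper, x))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
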