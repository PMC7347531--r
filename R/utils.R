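# Internal helpers: deterministic seed derivation and scoped RNG.

# Mix integers into a single seed < 2^31 - 1 with an LCG-style hash.
# Products stay below 2^53 so the arithmetic is exact in doubles.
mix_seed <- function(...) {
  parts <- unlist(list(...), use.names = FALSE)
  h <- 0
  for (k in parts) {
    if (is.character(k)) k <- sum(utf8ToInt(k) * seq_along(utf8ToInt(k)))
    h <- (h * 69069 + as.numeric(k) + 1) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)
warn_ <- function(...) warning(sprintf(...), call. = FALSE)
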