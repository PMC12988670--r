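# Internal helpers shared across modules.

# Deterministic 31-bit stream seed from a tuple of integers. Used so that
# fold assignment, restart initialisation and per-patient simulation draws
# come from independent, order-insensitive streams under one top-level seed.
mix_seed <- function(...) {
  v <- as.numeric(c(...))
  s <- 0
  for (x in v) s <- (s * 69069 + (x %% 2147483647) + 1) %% 2147483647
  as.integer(s)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

loc_names <- function(x, y) sprintf("x%dy%d", x, y)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_vf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
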