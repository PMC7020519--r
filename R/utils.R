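# Internal helpers shared across modules.

# Deterministic sub-seed from a root seed and a stage tag, kept inside the
# 32-bit integer range. Stable across platforms (pure integer arithmetic).
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (code in utf8ToInt(tag)) h <- (h * 31 + code) %% 2147483563
  as.integer((abs(seed) %% 2147483563 + h) %% 2147483563)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards so library code never perturbs user sessions.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

interaction_key <- function(tf, target) paste(tf, target, sep = "\t")

`%||%` <- function(a, b) if (is.null(a)) b else a
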