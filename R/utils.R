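# Internal helpers shared across modules.

# Derive a child RNG seed from a master seed and a stream index.
# Kept below 2^31 - 1 and within double precision (multipliers chosen so
# intermediate products stay < 2^53), so results are platform-independent.
derive_seed <- function(seed, stream) {
  seed <- as.numeric(seed) %% 2147483647
  s <- (seed * 48271 + as.numeric(stream) * 16807 + 1) %% 2147483647
  as.integer(s)
}

# Evaluate `code` under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = env, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = env), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }, add = TRUE)
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)

# scalar checks
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
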