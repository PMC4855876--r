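# Internal helpers shared across the package.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. seed = NULL means "use the current
# RNG stream" (no save/restore, no reseeding).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derivation: maps (master seed, index) to a seed in
# [1, 2^31 - 2] via a Lehmer-style congruential mix. Keyed on `index` so the
# same (seed, index) pair always yields the same stream, independent of any
# other indices in play.
derive_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  m <- 2147483647 # 2^31 - 1, prime
  s <- (as.double(seed) %% m) + 1
  k <- (as.double(index) %% m) + 1
  as.integer(((s * 48271 + k * 16807) %% (m - 1)) + 1)
}

# Significance codes following the four-level scheme used in classical cusp
# regression reporting: *** <0.00001, ** <0.001, * <0.01, . <0.05.
signif_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return("")
    if (pi < 1e-5) "***" else if (pi < 1e-3) "**" else if (pi < 1e-2) "*"
    else if (pi < 0.05) "." else ""
  }, character(1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
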