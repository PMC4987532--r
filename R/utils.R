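# Internal helpers: seeded RNG scoping and child-seed derivation.

# Evaluate `expr` under set.seed(seed) without disturbing the caller's RNG
# stream. All exported stochastic functions funnel through this.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
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
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seeds: a fixed counter scheme so that component k of a
# multi-part computation always sees the same stream regardless of how many
# other components run. Keeps every derived seed in [1, 2^31 - 2].
child_seeds <- function(seed, n, stream = 0L) {
  mod <- 2147483647  # 2^31 - 1, prime
  s <- (as.double(seed) %% mod) + 1
  ((s * 69069 + as.double(stream) * 48271 + seq_len(n) * 30269) %% (mod - 1)) + 1
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
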