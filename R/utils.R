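# Internal helpers shared across modules.

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so simulators are pure functions of (config, seed).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Summed-area table: S[i+1, j+1] = sum(m[1:i, 1:j]). Lets build_grid test
# "every pixel of this cell lies in the roi" in O(1) per cell.
summed_area <- function(m) {
  s <- apply(m, 2L, cumsum)
  s <- t(apply(s, 1L, cumsum))
  rbind(0, cbind(0, s))
}

sat_sum <- function(sat, r0, r1, c0, c1) {
  # half-open [r0, r1) x [c0, c1), 1-based
  sat[r1, c1] - sat[r0, c1] - sat[r1, c0] + sat[r0, c0]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
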