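# Internal helpers shared across modules.

# Evaluate `code` under set.seed(seed) without disturbing the caller's RNG
# stream. All seeded draws in the package go through this so generators are
# pure functions of (seed, parameters).
local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
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
  set.seed(as.integer(seed))
  force(code)
}

# Round half away from zero (positive arguments only), floor at `least`.
# Used wherever a sparsity or measurement count is derived from a ratio:
# SM and CF grids rarely hit integers exactly.
round_count <- function(x, least = 1L) {
  max(as.integer(least), as.integer(floor(x + 0.5)))
}

l2 <- function(x) sqrt(sum(x^2))

is_pow2 <- function(n) {
  n >= 1 && bitwAnd(as.integer(n), as.integer(n) - 1L) == 0L
}

check_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 ||
      x != floor(x)) {
    stop(sprintf("`%s` must be a single positive integer", name),
         call. = FALSE)
  }
  as.integer(x)
}
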