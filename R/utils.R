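# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, leaving the
# caller's RNG untouched. All generators route their randomness through this so
# they are pure functions of their arguments.
local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Splitmix-style child-seed derivation: deterministic, cheap, and stable under
# extension (child i never depends on how many children are requested). All
# arithmetic stays below 2^53 so doubles are exact.
derive_seed <- function(master_seed, index) {
  m <- 2147483629 # large prime < 2^31
  s <- (abs(as.numeric(master_seed)) + as.numeric(index) * 9973) %% m
  s <- (s * 7919 + 104729) %% m
  as.integer(s)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_unit_interval <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1]", name))
  }
  as.numeric(x)
}

is_symmetric_matrix <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) <= tol
}
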