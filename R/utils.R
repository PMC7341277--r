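# Internal helpers: validation conditions, seeded RNG scoping, seed splitting.

stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("cn_validation_error", "error", "condition")))
}

is_probability <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

assert_probability <- function(x, what) {
  if (!is_probability(x)) stop_validation("%s must be a single probability in [0, 1]", what)
  invisible(x)
}

# Derive a child seed from a root seed and a string key, so that every sampled
# quantity gets its own stream and adding one query never perturbs another.
# Kept below 2^31 - 1 (R integers are 32-bit).
split_seed <- function(seed, key) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_validation("seed must be a single finite number")
  chars <- utf8ToInt(key)
  h <- sum(chars * ((seq_along(chars) - 1L) %% 97 + 1) * 10007) %% 2147483647
  as.integer(((abs(seed) %% 2147483647) * 69069 + h) %% 2147483629 + 1)
}

# Evaluate `code` under set.seed(seed) without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
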