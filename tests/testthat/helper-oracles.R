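# Independent oracles and small fixtures shared across tests.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force noisy-OR oracle: enumerate every outcome of the independent
# mechanisms (leak plus one per active cause); the effect is present iff at
# least one mechanism fires. Deliberately independent of noisy_or_risk().
mechanism_risk_oracle <- function(leak, links, active = names(links)) {
  p <- c(leak, unname(links[active]))
  n <- length(p)
  total <- 0
  for (mask in seq_len(2^n) - 1L) {
    fired <- bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0
    if (any(fired)) total <- total + prod(ifelse(fired, p, 1 - p))
  }
  total
}

# Evidence lists used by the headline trio queries.
healthy_parents_evidence <- function() {
  list(P_sire = "F", P_dam = "F", D_sire = "F", E_sire = "F", A_sire = "F",
       D_dam = "F", E_dam = "F", A_dam = "F")
}

dam_signs_evidence <- function() {
  list(P_dam = "T", D_dam = "F", E_dam = "F", A_dam = "F")
}

# Deterministic gate limit: leak 0, genetic link 1.
deterministic_trio <- function(...) {
  build_trio(prior_group(leak = 0, link_ng = 0.1, link_g = 1), ...)
}
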