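#' Leaky noisy-OR gate
#'
#' A binary effect with independent binary causes: each active cause fires
#' its mechanism with its link probability, unmodelled causes fire with the
#' leak probability, and the effect is present iff at least one mechanism
#' fires. The effect probability for an active subset is therefore
#' \deqn{P(Y = T \mid X_p) = 1 - (1 - p_0)\prod_{i \in X_p}(1 - p_i).}
#'
#' @param leak Leak (background) probability \eqn{p_0} in [0, 1].
#' @param links Named numeric vector of link probabilities \eqn{p_i}, one per
#'   cause; names are the cause identifiers and must be unique. Boundary
#'   values 0 and 1 are legal (used by deterministic-limit scenarios).
#' @return An object of class `noisy_or`.
#' @examples
#' g <- noisy_or(0.01, c(diet = 0.1, exercise = 0.1))
#' noisy_or_risk(g, c("diet", "exercise"))  # 0.1981
#' @export
noisy_or <- function(leak, links = numeric()) {
  assert_probability(leak, "leak")
  if (length(links)) {
    if (!is.numeric(links) || is.null(names(links)) || any(!nzchar(names(links))))
      stop_validation("links must be a named numeric vector")
    if (anyDuplicated(names(links)))
      stop_validation("cause identifiers must be unique")
    if (any(!is.finite(links)) || any(links < 0) || any(links > 1))
      stop_validation("link probabilities must lie in [0, 1]")
  }
  structure(list(leak = leak, links = links), class = "noisy_or")
}

#' @export
print.noisy_or <- function(x, ...) {
  cat(sprintf("Leaky noisy-OR gate: leak = %.4g, %d cause(s)\n",
              x$leak, length(x$links)))
  if (length(x$links))
    print(round(x$links, 6))
  invisible(x)
}

#' Risk of the effect for an active cause subset
#'
#' @param spec A [noisy_or()] gate.
#' @param active Character vector of active cause identifiers (subset of the
#'   gate's causes; empty means all causes absent).
#' @return The probability \eqn{1 - (1-p_0)\prod_{i\in active}(1-p_i)}.
#' @export
noisy_or_risk <- function(spec, active = character()) {
  if (!inherits(spec, "noisy_or")) stop_validation("spec must be a noisy_or gate")
  active <- unique(as.character(active))
  unknown <- setdiff(active, names(spec$links))
  if (length(unknown))
    stop_validation("unknown cause identifier(s): %s", paste(unknown, collapse = ", "))
  if (!length(active)) return(spec$leak)  # empty product: risk is the leak, exactly
  1 - (1 - spec$leak) * prod(1 - spec$links[active])
}

#' Full conditional probability table of a noisy-OR gate
#'
#' Expands the gate into an explicit CPT over all \eqn{2^n} cause-state
#' combinations. Rows are indexed by named cause-state columns (values
#' `"T"`/`"F"`), never by integer position, so cause order never matters for
#' a given assignment.
#'
#' @param spec A [noisy_or()] gate with at most 16 causes.
#' @return A data frame with one `"T"`/`"F"` column per cause plus `p_true`
#'   and `p_false`; every row sums to 1.
#' @export
noisy_or_cpt <- function(spec) {
  if (!inherits(spec, "noisy_or")) stop_validation("spec must be a noisy_or gate")
  n <- length(spec$links)
  if (n > 16)
    stop_validation("CPT too large: %d causes (limit 16, %g rows)", n, 2^n)
  causes <- names(spec$links)
  grid <- expand.grid(rep(list(c("T", "F")), n), stringsAsFactors = FALSE)
  names(grid) <- causes
  if (n == 0) grid <- data.frame(row.names = 1)
  p_true <- vapply(seq_len(max(nrow(grid), 1L)), function(r) {
    active <- causes[as.character(grid[r, , drop = TRUE]) == "T"]
    noisy_or_risk(spec, active)
  }, 0)
  out <- cbind(grid, p_true = p_true, p_false = 1 - p_true)
  rownames(out) <- NULL
  out
}
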