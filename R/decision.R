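# Influence-diagram layer: utilities over the offspring genotype, expected
# utility of an evidence scenario, and comparison of mating alternatives.

validate_utilities <- function(utilities) {
  gs <- genotype_states()
  if (!is.numeric(utilities) || length(utilities) != 3L || any(!is.finite(utilities)))
    stop_validation("utilities must be 3 finite numbers (uAA, uAB, uBB)")
  if (is.null(names(utilities))) names(utilities) <- gs
  if (!setequal(names(utilities), gs))
    stop_validation("utility names must be AA, AB, BB")
  utilities[gs]
}

#' Expected utility of a mating scenario
#'
#' Scores an evidence configuration (a candidate mating, possibly with test
#' results and risk-factor states) by the expectation of a utility assigned
#' to each offspring genotype:
#' \eqn{EU = \sum_g P(G_{offsp} = g \mid evidence)\, u(g)}.
#'
#' @param net A `counselnet` containing the individual.
#' @param evidence Named list of observed states describing the alternative.
#' @param utilities Numeric vector `c(AA = , AB = , BB = )` of finite values.
#' @param individual Whose genotype carries the utility (default the
#'   offspring).
#' @return A single number between `min(utilities)` and `max(utilities)`.
#' @examples
#' net <- build_trio(prior_group(leak = 0, link_ng = 0.1, link_g = 1))
#' expected_utility(net, list(G_sire = "AA", G_dam = "AA"),
#'                  c(AA = 100, AB = 100, BB = 0))  # 100
#' @export
expected_utility <- function(net, evidence, utilities, individual = "offsp") {
  utilities <- validate_utilities(utilities)
  gname <- node_id("G", individual)
  if (!(gname %in% names(net$nodes)))
    stop_validation("no genotype node for individual %s", individual)
  if (gname %in% names(evidence))
    stop_validation("the utility-bearing genotype %s must not be evidence", gname)
  post <- posterior(net, gname, evidence)
  sum(post$prob * utilities[names(post$prob)])
}

#' Compare mating alternatives by expected utility
#'
#' Evaluates each alternative (an evidence set) with [expected_utility()] and
#' recommends the maximizer. Exact ties are broken lexicographically by
#' alternative label and flagged.
#'
#' @param net A `counselnet`.
#' @param alternatives Named list of evidence lists (unnamed lists get labels
#'   `alt1`, `alt2`, ...). Must be non-empty.
#' @inheritParams expected_utility
#' @return A `decision_report`: a table of expected utilities, the
#'   recommended alternative and a tie flag.
#' @export
compare_alternatives <- function(net, alternatives, utilities,
                                 individual = "offsp") {
  if (!is.list(alternatives) || length(alternatives) == 0L)
    stop_validation("alternatives must be a non-empty list of evidence sets")
  labels <- names(alternatives)
  if (is.null(labels)) labels <- paste0("alt", seq_along(alternatives))
  labels[!nzchar(labels)] <- paste0("alt", which(!nzchar(labels)))
  eu <- vapply(alternatives, expected_utility, 0, net = net,
               utilities = utilities, individual = individual)
  names(eu) <- labels
  best <- max(eu)
  winners <- sort(labels[eu >= best - 1e-12])
  structure(list(
    table = data.frame(alternative = labels, expected_utility = unname(eu),
                       row.names = NULL),
    recommended = winners[1L],
    tie = length(winners) > 1L,
    utilities = utilities),
    class = "decision_report")
}

#' @export
print.decision_report <- function(x, ...) {
  cat("Mating alternatives by expected utility\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("Recommended: %s%s\n", x$recommended,
              if (x$tie) " (tie, broken lexicographically)" else ""))
  invisible(x)
}
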