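# Exact inference: exhaustive enumeration (correctness oracle) and variable
# elimination with a min-degree ordering (the workhorse).

reduced_factors <- function(net, evidence) {
  lapply(net$nodes, function(nd) f_reduce(nd$cpt, evidence))
}

#' Unnormalized joint by exhaustive enumeration
#'
#' Multiplies every CPT (reduced on the evidence) into one table over all
#' unobserved nodes. The total mass equals the probability of the evidence.
#' Intended as a correctness oracle for small networks; refuses networks
#' with more than 24 nodes or over two million joint cells.
#'
#' @param net A `counselnet`.
#' @param evidence Named list of observed states.
#' @return A list with `joint` (array over unobserved nodes, unnormalized)
#'   and `mass` (the evidence probability).
#' @export
joint_enumeration <- function(net, evidence = list()) {
  if (!inherits(net, "counselnet")) stop_validation("net must be a counselnet")
  evidence <- validate_evidence(net, evidence)
  if (length(net$nodes) > 24L)
    stop_validation("network too large for exhaustive enumeration (%d nodes, limit 24)",
                    length(net$nodes))
  states <- net_states(net)
  cells <- prod(lengths(states[setdiff(names(net$nodes), names(evidence))]))
  if (cells > 2e6)
    stop_validation("joint state space too large for enumeration (%g cells)", cells)
  facs <- reduced_factors(net, evidence)
  joint <- Reduce(function(a, b) f_product(a, b, states), facs)
  mass <- if (f_is_scalar(joint)) as.numeric(joint) else sum(joint)
  if (!is.finite(mass) || mass <= 0)
    stop_validation("inconsistent evidence: zero total probability")
  list(joint = joint, mass = mass)
}

# Min-degree elimination ordering over the reduced factor list; ties broken
# lexicographically by node id for reproducibility.
pick_min_degree <- function(factor_vars, hidden) {
  degree <- vapply(hidden, function(v) {
    nb <- unique(unlist(factor_vars[vapply(factor_vars, function(vs) v %in% vs, TRUE)]))
    length(setdiff(nb, v))
  }, 0L)
  hidden[order(degree, hidden)][1L]
}

ve_marginal <- function(net, query, evidence) {
  states <- net_states(net)
  facs <- reduced_factors(net, evidence)
  const <- 1
  scal <- vapply(facs, f_is_scalar, TRUE)
  if (any(scal)) const <- prod(vapply(facs[scal], as.numeric, 0))
  facs <- facs[!scal]
  hidden <- setdiff(names(net$nodes), c(query, names(evidence)))
  while (length(hidden)) {
    fv <- lapply(facs, f_vars)
    v <- pick_min_degree(fv, hidden)
    inv <- vapply(fv, function(vs) v %in% vs, TRUE)
    prodf <- Reduce(function(a, b) f_product(a, b, states), facs[inv])
    newf <- f_sum_out(prodf, v)
    facs <- facs[!inv]
    if (f_is_scalar(newf)) const <- const * as.numeric(newf)
    else facs <- c(facs, list(newf))
    hidden <- setdiff(hidden, v)
  }
  final <- Reduce(function(a, b) f_product(a, b, states), facs)
  list(table = final * const, mass = sum(final) * const)
}

#' Posterior distribution of a node
#'
#' Exact posterior of one query node given evidence, by variable elimination
#' (default) or by the exhaustive-enumeration oracle. Evidence of zero joint
#' probability raises an explicit "inconsistent evidence" error rather than
#' returning an arbitrary normalized vector.
#'
#' @param net A `counselnet`.
#' @param query A node identifier, not itself observed.
#' @param evidence Named list of observed states, e.g.
#'   `list(G_offsp = "BB", D_dam = "F")`.
#' @param method `"ve"` (variable elimination) or `"enumeration"`.
#' @return A `counselnet_posterior`: the normalized distribution over the
#'   query node's states plus the evidence probability (`mass`).
#' @examples
#' net <- build_trio(prior_group(leak = 0.01, link_ng = 0.1, link_g = 0.9))
#' posterior(net, "G_sire", evidence = list(G_offsp = "BB"))
#' @export
posterior <- function(net, query, evidence = list(),
                      method = c("ve", "enumeration")) {
  method <- match.arg(method)
  if (!inherits(net, "counselnet")) stop_validation("net must be a counselnet")
  if (!is.character(query) || length(query) != 1L || !(query %in% names(net$nodes)))
    stop_validation("query must name one node of the network")
  evidence <- validate_evidence(net, evidence)
  if (query %in% names(evidence))
    stop_validation("query node %s is already observed", query)
  if (method == "enumeration") {
    je <- joint_enumeration(net, evidence)
    tab <- je$joint
    for (v in setdiff(f_vars(tab), query)) tab <- f_sum_out(tab, v)
    mass <- je$mass
  } else {
    res <- ve_marginal(net, query, evidence)
    tab <- res$table
    mass <- res$mass
  }
  if (!is.finite(mass) || mass <= 0)
    stop_validation("inconsistent evidence: zero total probability")
  prob <- as.numeric(tab) / sum(tab)
  names(prob) <- net$nodes[[query]]$states
  structure(list(query = query, prob = prob, evidence = evidence,
                 mass = mass, method = method,
                 cpt_mode = net$meta$cpt_mode),
            class = "counselnet_posterior")
}

#' @export
print.counselnet_posterior <- function(x, digits = 2, ...) {
  cat(sprintf("Posterior of %s%s\n", x$query,
              if (length(x$evidence))
                paste0(" | ", paste(names(x$evidence), unlist(x$evidence),
                                    sep = " = ", collapse = ", "))
              else " (no evidence)"))
  print(round(100 * x$prob, digits))
  cat(sprintf("  (percent; evidence probability %.6g)\n", x$mass))
  invisible(x)
}

#' Risk of clinical signs for one individual
#'
#' Convenience wrapper: the posterior probability that the individual's
#' phenotype node is `"T"` (clinical signs) given the supplied evidence,
#' typically a genotype or test result plus the states of the non-genetic
#' risk factors. When the genotype is given as certain evidence and the
#' network uses point-mean gates, this equals the noisy-OR risk of the
#' instantiated causes.
#'
#' @param net A `counselnet`.
#' @param individual Individual identifier.
#' @param evidence Named list of observed states.
#' @return The probability of clinical signs.
#' @export
counsel_risk <- function(net, individual, evidence = list()) {
  if (!(individual %in% names(net$individuals)))
    stop_validation("unknown individual: %s", individual)
  posterior(net, node_id("P", individual), evidence)$prob[["T"]]
}

#' Posterior averaged over gate-parameter draws
#'
#' An experimental alternative to averaging CPT entries: for each draw of the
#' leak/link parameters the trio network is rebuilt with those point values
#' and the posterior recomputed; the report gives the mean and spread of the
#' posterior probabilities across draws. One parameter realization applies
#' network-wide (the gate parameters are population quantities shared by all
#' individuals).
#'
#' @param priors A [prior_group()] to sample gate parameters from; the
#'   network template is the trio (extend via `...`).
#' @param query Node to query.
#' @param evidence Named list of observed states.
#' @param n_draws Number of parameter draws (>= 2).
#' @param seed Root seed (split per sampled quantity).
#' @param draw_mode `"independent"` (one draw per non-genetic cause) or
#'   `"shared_ng"`.
#' @param ... Further arguments passed to [build_trio()] when `priors` is a
#'   prior group (e.g. `genetic_model`, founder priors).
#' @return A list with `mean` and `sd` (named over the query states),
#'   `n_draws` and `seed`; deterministic given its inputs.
#' @export
posterior_over_draws <- function(priors, query, evidence = list(),
                                 n_draws = 200, seed = 1L,
                                 draw_mode = c("independent", "shared_ng"), ...) {
  draw_mode <- match.arg(draw_mode)
  if (!is.numeric(n_draws) || length(n_draws) != 1L || n_draws < 2)
    stop_validation("n_draws must be >= 2")
  n_draws <- as.integer(n_draws)
  if (inherits(priors, "prior_group")) {
    leak <- sample_prior(priors$leak, n_draws, split_seed(seed, "pd_leak"))
    genetic <- sample_prior(priors$link_g, n_draws, split_seed(seed, "pd_g"))
    if (draw_mode == "shared_ng") {
      shared <- sample_prior(priors$link_ng, n_draws, split_seed(seed, "pd_ng"))
      diet <- exercise <- age <- shared
    } else {
      diet <- sample_prior(priors$link_ng, n_draws, split_seed(seed, "pd_diet"))
      exercise <- sample_prior(priors$link_ng, n_draws, split_seed(seed, "pd_exercise"))
      age <- sample_prior(priors$link_ng, n_draws, split_seed(seed, "pd_age"))
    }
    base <- build_trio(prior_group(leak = 0.5, link_ng = 0.5, link_g = 0.5),
                       cpt_mode = "point_mean", ...)
    nets <- function(d) {
      gate <- list(leak = leak[d], genetic = genetic[d], diet = diet[d],
                   exercise = exercise[d], age = age[d])
      for (id in names(base$individuals))
        base$nodes[[node_id("P", id)]] <-
          phenotype_node(id, gate, base$meta$genetic_model)
      base
    }
  } else stop_validation("priors must be a prior_group")
  states <- nets(1L)$nodes[[query]]$states
  draws <- vapply(seq_len(n_draws), function(d) {
    posterior(nets(d), query, evidence)$prob
  }, stats::setNames(numeric(length(states)), states))
  list(mean = rowMeans(draws),
       sd = apply(draws, 1L, stats::sd),
       n_draws = n_draws, seed = seed, query = query)
}
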