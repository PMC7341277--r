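# Counseling-network assembly: pedigree DAG of genotype nodes plus, per
# individual, a noisy-OR phenotype node and binary risk-factor nodes
# (diet, exercise, age), with optional genetic-test nodes.

BINARY_STATES <- c("T", "F")
TEST_STATES <- c("pos", "neg")
NG_FACTORS <- c(diet = "D", exercise = "E", age = "A")

node_id <- function(kind, id) paste0(kind, "_", id)

make_node <- function(name, states, parents, cpt) {
  list(name = name, states = states, parents = parents, cpt = cpt)
}

# Root binary node with prior P(T) = p_true.
rf_node <- function(name, p_true = 0.5) {
  cpt <- array(c(p_true, 1 - p_true), dim = 2L,
               dimnames = stats::setNames(list(BINARY_STATES), name))
  make_node(name, BINARY_STATES, character(), cpt)
}

founder_genotype_node <- function(name, prior) {
  p <- parse_genotype_prior(prior)
  cpt <- array(p, dim = 3L, dimnames = stats::setNames(list(genotype_states()), name))
  make_node(name, genotype_states(), character(), cpt)
}

offspring_genotype_node <- function(name, sire_node, dam_node) {
  gs <- genotype_states()
  dn <- stats::setNames(list(gs, gs, gs), c(name, sire_node, dam_node))
  cpt <- array(0, dim = c(3L, 3L, 3L), dimnames = dn)
  for (s in gs) for (d in gs) cpt[, s, d] <- mendelian_transmission(s, d)
  make_node(name, gs, c(sire_node, dam_node), cpt)
}

# Is the genetic cause of the phenotype gate active for genotype `g`?
genetic_cause_active <- function(g, genetic_model) {
  if (genetic_model == "recessive") g == "BB" else g %in% c("AB", "BB")
}

# Phenotype CPT over parents (genotype, diet, exercise, age).
# gate: list(mode, draws for mc_mean) where draws holds per-realization
# sampled values l, g, diet, exercise, age (vectors of equal length; length
# 1 with the prior means for point_mean).
phenotype_node <- function(id, gate, genetic_model) {
  name <- node_id("P", id)
  gname <- node_id("G", id)
  fnames <- stats::setNames(paste0(NG_FACTORS, "_", id), names(NG_FACTORS))
  gs <- genotype_states()
  dn <- c(stats::setNames(list(BINARY_STATES, gs), c(name, gname)),
          stats::setNames(rep(list(BINARY_STATES), 3), fnames))
  cpt <- array(0, dim = c(2L, 3L, 2L, 2L, 2L), dimnames = dn)
  combos <- expand.grid(g = gs, diet = BINARY_STATES, exercise = BINARY_STATES,
                        age = BINARY_STATES, stringsAsFactors = FALSE)
  for (r in seq_len(nrow(combos))) {
    surv <- 1 - gate$leak
    any_active <- FALSE
    if (genetic_cause_active(combos$g[r], genetic_model)) {
      surv <- surv * (1 - gate$genetic)
      any_active <- TRUE
    }
    for (fac in names(NG_FACTORS))
      if (combos[[fac]][r] == "T") {
        surv <- surv * (1 - gate[[fac]])
        any_active <- TRUE
      }
    # all causes absent: the row is exactly (leak, 1 - leak)
    p <- if (any_active) mean(1 - surv) else mean(gate$leak)
    cpt[, combos$g[r], combos$diet[r], combos$exercise[r], combos$age[r]] <-
      c(p, 1 - p)
  }
  make_node(name, BINARY_STATES, c(gname, fnames), cpt)
}

# Resolve a prior_group into gate value vectors for CPT construction.
# point_mean: length-1 vectors at the prior means. mc_mean: `draws` sampled
# realizations; the CPT entry becomes the Monte Carlo average of the
# per-draw noisy-OR row. With shared_ng draws one non-genetic link draw is
# reused for diet, exercise and age within a realization.
resolve_gate <- function(priors, cpt_mode, draws, seed, draw_mode) {
  if (cpt_mode == "point_mean") {
    v <- list(leak = beta_mean(priors$leak), genetic = beta_mean(priors$link_g))
    for (fac in names(NG_FACTORS)) v[[fac]] <- beta_mean(priors$link_ng)
    return(v)
  }
  v <- list(leak = sample_prior(priors$leak, draws, split_seed(seed, "gate_leak")),
            genetic = sample_prior(priors$link_g, draws, split_seed(seed, "gate_g")))
  if (draw_mode == "shared_ng") {
    shared <- sample_prior(priors$link_ng, draws, split_seed(seed, "gate_ng"))
    for (fac in names(NG_FACTORS)) v[[fac]] <- shared
  } else {
    for (fac in names(NG_FACTORS))
      v[[fac]] <- sample_prior(priors$link_ng, draws,
                               split_seed(seed, paste0("gate_", fac)))
  }
  v
}

new_counselnet <- function(nodes, individuals, meta) {
  structure(list(nodes = nodes, individuals = individuals, meta = meta),
            class = "counselnet")
}

net_states <- function(net) lapply(net$nodes, `[[`, "states")

# Topological order of node names; errors on a cycle.
topological_order <- function(net) {
  remaining <- names(net$nodes)
  parents <- lapply(net$nodes, `[[`, "parents")
  order <- character()
  while (length(remaining)) {
    ready <- remaining[vapply(parents[remaining],
                              function(p) all(p %in% order), TRUE)]
    if (!length(ready))
      stop_validation("network contains a directed cycle (feedback loops are not representable)")
    order <- c(order, sort(ready))
    remaining <- setdiff(remaining, ready)
  }
  order
}

validate_counselnet <- function(net) {
  for (nd in net$nodes) {
    missing <- setdiff(nd$parents, names(net$nodes))
    if (length(missing))
      stop_validation("node %s has unknown parent(s): %s", nd$name,
                      paste(missing, collapse = ", "))
    tot <- if (length(dim(nd$cpt)) == 1L) sum(nd$cpt)
           else apply(nd$cpt, seq_along(dim(nd$cpt))[-1L], sum)
    if (any(abs(tot - 1) > 1e-12))
      stop_validation("CPT of node %s has rows not summing to 1", nd$name)
  }
  topological_order(net)
  invisible(net)
}

add_individual <- function(net, id, sire = NULL, dam = NULL, prior = "uniform",
                           rf_prior = 0.5) {
  if (id %in% names(net$individuals))
    stop_validation("duplicate individual id: %s", id)
  founder <- is.null(sire) && is.null(dam)
  if (!founder) {
    if (is.null(sire) || is.null(dam))
      stop_validation("a child needs both a sire and a dam")
    if (identical(sire, dam))
      stop_validation("sire and dam must be two distinct individuals")
    for (p in c(sire, dam))
      if (!(p %in% names(net$individuals)))
        stop_validation("unknown parent '%s' for individual '%s'", p, id)
  }
  gname <- node_id("G", id)
  gnode <- if (founder) founder_genotype_node(gname, prior)
           else offspring_genotype_node(gname, node_id("G", sire), node_id("G", dam))
  nodes <- list(gnode)
  for (fac in names(NG_FACTORS))
    nodes <- c(nodes, list(rf_node(paste0(NG_FACTORS[[fac]], "_", id), rf_prior)))
  nodes <- c(nodes, list(phenotype_node(id, net$meta$gate, net$meta$genetic_model)))
  names(nodes) <- vapply(nodes, `[[`, "", "name")
  net$nodes <- c(net$nodes, nodes)
  net$individuals[[id]] <- list(id = id, sire = sire, dam = dam,
                                prior = if (founder) prior else NULL)
  net
}

#' Build the sire-dam-offspring counseling network
#'
#' Constructs the three-individual network: genotype nodes linked by a
#' Mendelian transmission CPT, and per individual a phenotype node governed
#' by a leaky noisy-OR gate over four causes (genetic status, diet, exercise,
#' age) plus the three binary risk-factor root nodes. Founder genotypes carry
#' uniform priors by default (one third each state).
#'
#' With `cpt_mode = "point_mean"` the gate probabilities are the prior means
#' (deterministic and fast). With `"mc_mean"` each phenotype-CPT entry is the
#' Monte Carlo average of the noisy-OR row over `draws` sampled leak/link
#' realizations; with independent draws per cause this coincides with
#' `point_mean` up to Monte Carlo error, while `draw_mode = "shared_ng"`
#' reuses one non-genetic link draw across diet, exercise and age.
#'
#' @param priors A [prior_group()]; point probabilities give exact gates.
#' @param cpt_mode `"point_mean"` or `"mc_mean"`.
#' @param draws,seed Monte Carlo settings for `mc_mean`.
#' @param draw_mode `"independent"` or `"shared_ng"` (mc_mean only).
#' @param genetic_model `"recessive"` (genetic cause active iff BB; the
#'   degenerative-myelopathy default) or `"dominant"` (active for AB or BB).
#' @param sire_prior,dam_prior Founder genotype priors: `"uniform"`,
#'   `"hwe(q)"`, a fixed state, or a numeric 3-vector.
#' @param rf_prior Prior P(T) of the risk-factor root nodes; counseling
#'   queries normally instantiate these as evidence, so it only matters for
#'   unqueried individuals.
#' @return A `counselnet` object.
#' @examples
#' net <- build_trio(prior_group(leak = 0, link_ng = 0.1, link_g = 1))
#' posterior(net, "G_offsp", evidence = list(G_sire = "AB", G_dam = "AB"))
#' @export
build_trio <- function(priors, cpt_mode = c("point_mean", "mc_mean"),
                       draws = 10000, seed = 1L,
                       draw_mode = c("independent", "shared_ng"),
                       genetic_model = c("recessive", "dominant"),
                       sire_prior = "uniform", dam_prior = "uniform",
                       rf_prior = 0.5) {
  cpt_mode <- match.arg(cpt_mode)
  draw_mode <- match.arg(draw_mode)
  genetic_model <- match.arg(genetic_model)
  if (!inherits(priors, "prior_group")) stop_validation("priors must be a prior_group")
  gate <- resolve_gate(priors, cpt_mode, draws, seed, draw_mode)
  meta <- list(priors = priors, cpt_mode = cpt_mode, draws = draws, seed = seed,
               draw_mode = draw_mode, genetic_model = genetic_model,
               gate = gate, rf_prior = rf_prior)
  net <- new_counselnet(list(), list(), meta)
  net <- add_individual(net, "sire", prior = sire_prior, rf_prior = rf_prior)
  net <- add_individual(net, "dam", prior = dam_prior, rf_prior = rf_prior)
  net <- add_individual(net, "offsp", sire = "sire", dam = "dam",
                        rf_prior = rf_prior)
  validate_counselnet(net)
}

#' Extend a counseling network with a relative
#'
#' Adds one individual — a founder (no parents stated) or a child of two
#' individuals already in the network — together with its genotype,
#' phenotype and risk-factor nodes, built with the network's stored gate
#' parameterization. Existing CPTs are untouched, so posteriors of queries
#' that do not involve the new nodes are unchanged.
#'
#' @param net A `counselnet`.
#' @param id New unique individual identifier.
#' @param sire,dam Parent identifiers (both or neither).
#' @param prior Founder genotype prior (ignored for a child).
#' @return The extended `counselnet`.
#' @export
add_relative <- function(net, id, sire = NULL, dam = NULL, prior = "uniform") {
  if (!inherits(net, "counselnet")) stop_validation("net must be a counselnet")
  net <- add_individual(net, id, sire = sire, dam = dam, prior = prior,
                        rf_prior = net$meta$rf_prior)
  validate_counselnet(net)
}

#' Attach a genetic-test node to an individual
#'
#' Adds a binary (`"pos"`/`"neg"`) test node whose only parent is the
#' individual's true genotype. Under the default `"detect_bb"` semantics the
#' test targets the homozygous mutant state: P(pos | BB) = sensitivity and
#' P(pos | AA) = P(pos | AB) = 1 - specificity. Under `"detect_allele"` a
#' carrier also triggers the test: P(pos | AB) = sensitivity.
#'
#' @param net A `counselnet`.
#' @param id Individual identifier.
#' @param sensitivity,specificity Test operating characteristics in [0, 1].
#' @param semantics `"detect_bb"` or `"detect_allele"`.
#' @return The extended `counselnet`; the node is named `T_<id>`.
#' @export
add_test_node <- function(net, id, sensitivity, specificity,
                          semantics = c("detect_bb", "detect_allele")) {
  semantics <- match.arg(semantics)
  if (!inherits(net, "counselnet")) stop_validation("net must be a counselnet")
  if (!(id %in% names(net$individuals)))
    stop_validation("unknown individual: %s", id)
  assert_probability(sensitivity, "sensitivity")
  assert_probability(specificity, "specificity")
  name <- node_id("T", id)
  if (name %in% names(net$nodes))
    stop_validation("individual %s already has a test node", id)
  gname <- node_id("G", id)
  p_pos <- c(AA = 1 - specificity,
             AB = if (semantics == "detect_allele") sensitivity else 1 - specificity,
             BB = sensitivity)
  dn <- stats::setNames(list(TEST_STATES, genotype_states()), c(name, gname))
  cpt <- array(rbind(p_pos, 1 - p_pos), dim = c(2L, 3L), dimnames = dn)
  net$nodes[[name]] <- make_node(name, TEST_STATES, gname, cpt)
  validate_counselnet(net)
}

# Structure audit used by summary() and tests: node counts per individual.
network_audit <- function(net) {
  ids <- names(net$individuals)
  data.frame(
    individual = ids,
    genotype = vapply(ids, function(i) node_id("G", i) %in% names(net$nodes), TRUE),
    phenotype = vapply(ids, function(i) node_id("P", i) %in% names(net$nodes), TRUE),
    n_risk_factors = vapply(ids, function(i) {
      sum(paste0(NG_FACTORS, "_", i) %in% names(net$nodes))
    }, 0L),
    test = vapply(ids, function(i) node_id("T", i) %in% names(net$nodes), TRUE),
    row.names = NULL)
}

validate_evidence <- function(net, evidence) {
  if (length(evidence) == 0L) return(invisible(list()))
  if (is.null(names(evidence)) || any(!nzchar(names(evidence))))
    stop_validation("evidence must be a named list of node = state")
  unknown <- setdiff(names(evidence), names(net$nodes))
  if (length(unknown))
    stop_validation("evidence on unknown node(s): %s", paste(unknown, collapse = ", "))
  for (nm in names(evidence)) {
    st <- as.character(evidence[[nm]])
    if (length(st) != 1L || !(st %in% net$nodes[[nm]]$states))
      stop_validation("invalid state '%s' for node %s (states: %s)",
                      paste(st, collapse = ","), nm,
                      paste(net$nodes[[nm]]$states, collapse = ", "))
  }
  invisible(lapply(evidence, as.character))
}
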