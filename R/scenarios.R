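# Packaged scenario fixtures, a random-scenario generator for property
# tests, and the reproduction-report runner.

#' Packaged counseling scenarios
#'
#' Loads the scenario fixtures shipped with the package: the seven
#' illustrative prior groups, the forward-risk grid, the named trio queries
#' (healthy parents, affected dam, allele-frequency variants, backward query
#' from a tested offspring) and the utility settings. Each fixture carries an
#' `expected` block with a provenance tag (`paper`-reported reference value,
#' `derived` closed form, or `trivial`) and the parameterization under which
#' the value is reproduced.
#'
#' @return A named list of `cn_scenario` objects.
#' @export
packaged_scenarios <- function() {
  dir <- system.file("extdata", "scenarios", package = "counselnet")
  files <- sort(list.files(dir, pattern = "\\.yaml$", full.names = TRUE))
  out <- lapply(files, read_scenario)
  names(out) <- vapply(out, `[[`, "", "label")
  out
}

#' Reference values the packaged parameterizations do not reproduce
#'
#' Five externally quoted values for these scenario families cannot be
#' obtained from any stated parameterization of this model (their generating
#' configuration — draw counts, seeds, exact Beta shapes — is unavailable);
#' they are listed explicitly rather than silently dropped. See the methods
#' vignette for the analysis.
#'
#' @return A data frame with columns `quantity`, `reference_value`,
#'   `closest_computed`, `status`, `note`.
#' @export
documented_discrepancies <- function() {
  data.frame(
    quantity = c(
      "offspring BB | healthy parents, all non-genetic factors T",
      "parent BB | offspring clinically ill, offspring factors all F",
      "parent BB | offspring clinically ill, offspring factors all T",
      "expected utility, untested healthy mating, u = (100, 100, 0)",
      "expected utility, untested healthy mating, u = (100, 50, 0)"),
    reference_value = c(6.42, 100, 66.5, 93.69, 74.88),
    closest_computed = c(6.25, 66.67, NA, 93.75, 75.00),
    status = "not reproduced",
    note = c(
      "non-genetic factors cancel in the healthy-parent likelihood ratio for any point-value gate; only parameter-averaged posteriors move, and none reaches 6.42",
      "a single parent's BB posterior cannot exceed 2/3 given offspring-only evidence under uniform founder priors",
      "no stated parameterization reproduces this value; possibly extra evidence was set in the original interactive session",
      "implies P(offspring BB) ~ 6.31% where every stated parameterization gives 6.25%",
      "implies the same unexplained posterior as the 93.69 value"),
    stringsAsFactors = FALSE)
}

# Default tolerance (percentage points / utility units) when a fixture does
# not state one: agreement to two printed decimals.
expected_tolerance <- function(expected) {
  if (!is.null(expected$tolerance)) expected$tolerance else 0.005
}

report_row <- function(scenario, quantity, expected, computed, status,
                       provenance = NA_character_, note = NA_character_) {
  data.frame(scenario = scenario, quantity = quantity,
             expected = expected, computed = computed, status = status,
             provenance = provenance, note = note, stringsAsFactors = FALSE)
}

#' Run one scenario and compare against its expected values
#'
#' @param sc A `cn_scenario`.
#' @param draws,seed Monte Carlo settings for `risk_table` scenarios and
#'   `mc_mean` networks.
#' @return A data frame of report rows (scenario, quantity, expected,
#'   computed, status, provenance, note).
#' @export
run_scenario <- function(sc, draws = 10000, seed = 1L) {
  if (!inherits(sc, "cn_scenario")) stop_validation("sc must be a cn_scenario")
  prov <- if (is.null(sc$expected$provenance)) NA_character_ else sc$expected$provenance
  note <- if (is.null(sc$expected$note)) NA_character_ else sc$expected$note
  tol <- expected_tolerance(sc$expected)
  if (sc$type == "query") {
    net <- scenario_network(sc, draws = draws, seed = seed)
    post <- posterior(net, sc$query, sc$evidence)
    rows <- lapply(names(post$prob), function(st) {
      exp_v <- if (!is.null(sc$expected$values[[st]]))
        sc$expected$values[[st]] else NA_real_
      comp <- 100 * post$prob[[st]]
      status <- if (is.na(exp_v)) "computed"
                else if (abs(comp - exp_v) <= tol + 1e-9) "reproduced"
                else "mismatch"
      report_row(sc$label, paste0(sc$query, " = ", st, " (%)"),
                 exp_v, comp, status, prov, note)
    })
    do.call(rbind, rows)
  } else if (sc$type == "utility") {
    net <- scenario_network(sc, draws = draws, seed = seed)
    u <- unlist(sc$utilities)
    eu <- expected_utility(net, sc$evidence, u)
    exp_v <- if (!is.null(sc$expected$value)) sc$expected$value else NA_real_
    status <- if (is.na(exp_v)) "computed"
              else if (abs(eu - exp_v) <= tol + 1e-9) "reproduced"
              else "mismatch"
    report_row(sc$label,
               sprintf("expected utility (u = %s)", paste(u, collapse = "/")),
               exp_v, eu, status, prov, note)
  } else {  # risk_table: ordering property, not cell values
    tab <- risk_table(scenario_prior_group(sc), n_draws = draws, seed = seed)
    m <- stats::setNames(tab$mean, tab$risk)
    ok <- m[["NG1"]] < m[["NG2"]] && m[["NG2"]] < m[["NG3"]] &&
      all(m[paste0(c("NG1", "NG2", "NG3"), "+G")] >
            m[c("NG1", "NG2", "NG3")]) && m[["G"]] > 0
    report_row(sc$label, "risk ordering NG1<NG2<NG3 and X+G>X",
               NA_real_, NA_real_,
               if (ok) "property holds" else "property violated",
               prov, note)
  }
}

#' Reproduction report over all packaged scenarios
#'
#' Runs every packaged fixture, compares computed values with their tagged
#' expectations, and appends the documented-discrepancy rows so that
#' irreproducible reference values are reported explicitly, never silently.
#'
#' @param scenarios List of `cn_scenario` (default: all packaged).
#' @param draws,seed Monte Carlo settings.
#' @return A `cn_report` data frame.
#' @export
run_scenarios <- function(scenarios = packaged_scenarios(), draws = 10000,
                          seed = 1L) {
  rows <- do.call(rbind, lapply(scenarios, run_scenario, draws = draws,
                                seed = seed))
  dd <- documented_discrepancies()
  rows <- rbind(rows, data.frame(
    scenario = "documented_discrepancies", quantity = dd$quantity,
    expected = dd$reference_value, computed = dd$closest_computed,
    status = "not reproduced — see documented discrepancies",
    provenance = "reference", note = dd$note, stringsAsFactors = FALSE))
  rownames(rows) <- NULL
  class(rows) <- c("cn_report", "data.frame")
  rows
}

#' @export
print.cn_report <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  y$expected <- round(y$expected, 4)
  y$computed <- round(y$computed, 4)
  y$note <- NULL
  print(y, row.names = FALSE, right = FALSE)
  invisible(x)
}

#' Random counseling scenario for property tests
#'
#' Generates a seed-deterministic random pedigree (first two individuals are
#' founders, later ones founders or children of existing pairs), random
#' founder genotype priors, noisy-OR phenotype gates whose leak/link values
#' are drawn from Beta priors with random feasible moments, random evidence
#' rejection-checked to have nonzero joint probability, and a random
#' unobserved query node. Node count is capped at `node_budget` (phenotype
#' and factor nodes beyond the budget are dropped) so the enumeration oracle
#' stays cheap.
#'
#' @param seed Integer seed; identical seeds give identical scenarios.
#' @param n_individuals Number of individuals, 3 to 5.
#' @param node_budget Maximum number of nodes (default 12).
#' @return A list with `label`, `net`, `evidence`, `query`, `seed`.
#' @export
random_scenario <- function(seed, n_individuals = 3, node_budget = 12) {
  if (!is.numeric(n_individuals) || n_individuals < 3 || n_individuals > 5)
    stop_validation("n_individuals must be between 3 and 5")
  n_individuals <- as.integer(n_individuals)
  with_seed(split_seed(seed, "random_scenario"), {
    ids <- paste0("ind", seq_len(n_individuals))
    meta <- list(cpt_mode = "point_mean", genetic_model = "recessive",
                 gate = NULL, rf_prior = 0.5)
    net <- new_counselnet(list(), list(), meta)
    rand_prior <- function() {
      p <- stats::rgamma(3, 1)
      p / sum(p)
    }
    for (k in seq_len(n_individuals)) {
      id <- ids[k]
      if (k <= 2 || stats::runif(1) < 0.4) {
        gnode <- founder_genotype_node(node_id("G", id), rand_prior())
        net$individuals[[id]] <- list(id = id, sire = NULL, dam = NULL,
                                      prior = "random")
      } else {
        par <- sample(ids[seq_len(k - 1)], 2)
        gnode <- offspring_genotype_node(node_id("G", id),
                                         node_id("G", par[1]),
                                         node_id("G", par[2]))
        net$individuals[[id]] <- list(id = id, sire = par[1], dam = par[2])
      }
      net$nodes[[gnode$name]] <- gnode
    }
    rand_gate_value <- function() {
      m <- stats::runif(1, 0.05, 0.95)
      s <- sqrt(stats::runif(1, 0.1, 0.8) * m * (1 - m))
      sample_prior(beta_from_moments(m, s), 1)
    }
    for (id in ids) {
      if (length(net$nodes) >= node_budget) break
      if (stats::runif(1) < 0.6) {
        n_fac <- min(sample(0:2, 1), node_budget - length(net$nodes) - 1L)
        facs <- if (n_fac > 0) paste0("F", seq_len(n_fac), "_", id) else character()
        for (f in facs)
          net$nodes[[f]] <- rf_node(f, stats::runif(1, 0.1, 0.9))
        pname <- node_id("P", id)
        link_f <- stats::setNames(vapply(facs, function(f) rand_gate_value(), 0),
                                  facs)
        net$nodes[[pname]] <- gate_node(pname, node_id("G", id), facs,
                                        leak = rand_gate_value(),
                                        link_g = rand_gate_value(),
                                        link_f = link_f)
      }
    }
    validate_counselnet(net)
    evidence <- list()
    for (try in seq_len(100)) {
      cand <- list()
      for (nm in names(net$nodes)) {
        if (stats::runif(1) < 0.35) {
          st <- net$nodes[[nm]]$states
          cand[[nm]] <- st[sample.int(length(st), 1)]
        }
      }
      if (length(cand) == length(net$nodes)) cand[[1]] <- NULL
      mass <- tryCatch(joint_enumeration(net, cand)$mass, error = function(e) 0)
      if (mass > 1e-9) { evidence <- cand; break }
    }
    free <- setdiff(names(net$nodes), names(evidence))
    query <- free[sample.int(length(free), 1)]
    list(label = sprintf("random_%d", as.integer(seed)), net = net,
         evidence = evidence, query = query, seed = seed)
  })
}

# Noisy-OR CPT node with a genotype parent (recessive genetic cause) and an
# arbitrary set of binary factor parents; used by the random generator.
gate_node <- function(name, gparent, factor_parents, leak, link_g, link_f) {
  gs <- genotype_states()
  dn <- c(stats::setNames(list(BINARY_STATES, gs), c(name, gparent)),
          stats::setNames(rep(list(BINARY_STATES), length(factor_parents)),
                          factor_parents))
  cpt <- array(0, dim = lengths(dn), dimnames = dn)
  combos <- expand.grid(dn[-1L], stringsAsFactors = FALSE)
  for (r in seq_len(nrow(combos))) {
    surv <- (1 - leak)
    if (combos[[gparent]][r] == "BB") surv <- surv * (1 - link_g)
    for (f in factor_parents)
      if (combos[[f]][r] == "T") surv <- surv * (1 - link_f[[f]])
    idx <- c(list(cpt), list(TRUE), as.list(unname(unlist(combos[r, , drop = FALSE]))),
             list(value = c(1 - surv, surv)))
    cpt <- do.call(`[<-`, idx)
  }
  make_node(name, BINARY_STATES, c(gparent, factor_parents), cpt)
}
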