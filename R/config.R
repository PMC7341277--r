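# Structured-text (YAML) scenario configuration: reading, normalization,
# writing, and conversion into networks. Percentages ("10%") are accepted
# on input and stored as fractions; evidence states are "T"/"F" strings
# (bare T/F in YAML parse as logicals and are normalized back).

parse_fraction <- function(x, what) {
  if (is.character(x) && length(x) == 1L) {
    if (grepl("%$", x)) return(as.numeric(sub("%$", "", x)) / 100)
    x <- as.numeric(x)
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_validation("%s must be a number or a percentage string", what)
  x
}

# Canonical form of one prior component: a bare fraction (point mass) or
# list(alpha =, beta =). Shapes are canonicalized to 12 significant digits
# so that load -> save -> load is the exact identity.
normalize_prior_component <- function(x, what) {
  if (is.numeric(x) || is.character(x)) {
    p <- parse_fraction(x, what)
    assert_probability(p, what)
    return(signif(p, 12))
  }
  if (is.list(x)) {
    if (!is.null(x$alpha) && !is.null(x$beta)) {
      spec <- beta_spec(x$alpha, x$beta)
      return(list(alpha = signif(spec$alpha, 12), beta = signif(spec$beta, 12)))
    }
    if (!is.null(x$mean) && !is.null(x$nu)) {
      spec <- beta_from_mean_concentration(parse_fraction(x$mean, what), x$nu)
      return(list(alpha = signif(spec$alpha, 12), beta = signif(spec$beta, 12)))
    }
    if (!is.null(x$mean) && !is.null(x$sd)) {
      spec <- beta_from_moments(parse_fraction(x$mean, what),
                                parse_fraction(x$sd, what))
      return(list(alpha = signif(spec$alpha, 12), beta = signif(spec$beta, 12)))
    }
  }
  stop_validation("unrecognized prior specification for %s", what)
}

as_prior <- function(x) {
  if (is.numeric(x) && length(x) == 1L) x
  else beta_spec(x$alpha, x$beta)
}

normalize_state <- function(x) {
  if (is.logical(x)) return(if (x) "T" else "F")
  x <- as.character(x)
  if (x %in% c("TRUE", "yes", "true")) "T"
  else if (x %in% c("FALSE", "no", "false")) "F"
  else x
}

normalize_scenario <- function(x) {
  known <- c("label", "type", "network", "evidence", "query", "utilities",
             "expected")
  extra <- setdiff(names(x), known)
  if (length(extra))
    stop_validation("unknown scenario key(s): %s", paste(extra, collapse = ", "))
  if (is.null(x$label) || is.null(x$type))
    stop_validation("scenario needs 'label' and 'type' keys")
  if (!(x$type %in% c("query", "risk_table", "utility")))
    stop_validation("scenario '%s': unknown type '%s'", x$label, x$type)
  if (!is.null(x$network$priors)) {
    for (nm in names(x$network$priors))
      x$network$priors[[nm]] <-
        normalize_prior_component(x$network$priors[[nm]],
                                  paste0("priors$", nm))
  }
  if (!is.null(x$evidence))
    x$evidence <- lapply(x$evidence, normalize_state)
  if (!is.null(x$utilities)) {
    u <- unlist(x$utilities)
    x$utilities <- as.list(validate_utilities(u))
  }
  if (!is.null(x$expected$values))
    x$expected$values <- lapply(x$expected$values, as.numeric)
  structure(x, class = "cn_scenario")
}

#' Read and write scenario configurations
#'
#' Scenario files are YAML with keys `label`, `type` (`query`, `risk_table`
#' or `utility`), `network` (priors, founders, genetic model, optional
#' relatives and test nodes), `evidence`, `query`, `utilities` and an
#' optional `expected` block recording a reference value with its provenance
#' tag. Priors may be given as `{mean, sd}`, `{mean, nu}`, `{alpha, beta}`
#' or a bare value; percentage strings like `"10%"` are accepted and stored
#' as fractions. Loading normalizes the configuration, so load-save-load is
#' the identity.
#'
#' @param path Path to a YAML file.
#' @return `read_scenario` returns a `cn_scenario` object.
#' @export
read_scenario <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop_validation("scenario file not found: %s", paste(path, collapse = ""))
  normalize_scenario(yaml::read_yaml(path))
}

#' @rdname read_scenario
#' @param scenario A `cn_scenario`.
#' @export
write_scenario <- function(scenario, path) {
  if (!inherits(scenario, "cn_scenario"))
    stop_validation("scenario must be a cn_scenario")
  yaml::write_yaml(unclass(scenario), path, precision = 15)
  invisible(path)
}

# Build the counseling network described by a scenario's `network` block.
scenario_network <- function(sc, draws = 2000, seed = 1L) {
  nw <- sc$network
  if (is.null(nw$priors))
    stop_validation("scenario '%s' has no network priors", sc$label)
  pg <- prior_group(leak = as_prior(nw$priors$leak),
                    link_ng = as_prior(nw$priors$link_ng),
                    link_g = as_prior(nw$priors$link_g),
                    label = sc$label)
  net <- build_trio(
    pg,
    cpt_mode = if (is.null(nw$cpt_mode)) "point_mean" else nw$cpt_mode,
    draws = if (is.null(nw$draws)) draws else nw$draws,
    seed = seed,
    genetic_model = if (is.null(nw$genetic_model)) "recessive" else nw$genetic_model,
    sire_prior = if (is.null(nw$founders$sire)) "uniform" else nw$founders$sire,
    dam_prior = if (is.null(nw$founders$dam)) "uniform" else nw$founders$dam)
  for (rel in nw$relatives)
    net <- add_relative(net, rel$id, sire = rel$sire, dam = rel$dam,
                        prior = if (is.null(rel$prior)) "uniform" else rel$prior)
  for (tn in nw$test_nodes)
    net <- add_test_node(net, tn$individual, tn$sensitivity, tn$specificity,
                         semantics = if (is.null(tn$semantics)) "detect_bb"
                                     else tn$semantics)
  net
}

scenario_prior_group <- function(sc) {
  prior_group(leak = as_prior(sc$network$priors$leak),
              link_ng = as_prior(sc$network$priors$link_ng),
              link_g = as_prior(sc$network$priors$link_g),
              label = sc$label)
}

#' @export
print.cn_scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s' (%s)\n", x$label, x$type))
  if (!is.null(x$query)) cat("  query:", x$query, "\n")
  if (length(x$evidence))
    cat("  evidence:", paste(names(x$evidence), unlist(x$evidence),
                             sep = " = ", collapse = ", "), "\n")
  if (!is.null(x$expected$provenance))
    cat("  expected values tagged:", x$expected$provenance, "\n")
  invisible(x)
}
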