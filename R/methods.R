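# S3 methods for the counselnet network object.

#' @export
print.counselnet <- function(x, ...) {
  cat(sprintf("Counseling network: %d individual(s), %d node(s)\n",
              length(x$individuals), length(x$nodes)))
  for (ind in x$individuals) {
    cat(sprintf("  %-8s %s\n", ind$id,
                if (is.null(ind$sire)) sprintf("founder (prior: %s)",
                                               format_prior(ind$prior))
                else sprintf("child of %s x %s", ind$sire, ind$dam)))
  }
  cat(sprintf("  gate CPTs: %s, genetic model %s\n",
              x$meta$cpt_mode, x$meta$genetic_model))
  invisible(x)
}

format_prior <- function(p) {
  if (is.character(p)) p
  else if (is.numeric(p)) paste(round(p, 3), collapse = "/")
  else if (is.list(p) && !is.null(p$hwe)) sprintf("hwe(%g)", p$hwe)
  else if (is.list(p) && !is.null(p$fixed)) p$fixed
  else "custom"
}

#' @export
summary.counselnet <- function(object, ...) {
  out <- list(audit = network_audit(object),
              n_nodes = length(object$nodes),
              cpt_mode = object$meta$cpt_mode,
              genetic_model = object$meta$genetic_model,
              topological_order = topological_order(object))
  class(out) <- "summary.counselnet"
  out
}

#' @export
print.summary.counselnet <- function(x, ...) {
  cat(sprintf("Counseling network: %d nodes (%s gates, %s model)\n",
              x$n_nodes, x$cpt_mode, x$genetic_model))
  print(x$audit, row.names = FALSE)
  invisible(x)
}

#' Posterior prediction for a counseling network
#'
#' `predict` on a `counselnet` is exact posterior inference: it forwards to
#' [posterior()].
#'
#' @param object A `counselnet`.
#' @param query Node identifier to query.
#' @param evidence Named list of observed states.
#' @param ... Passed to [posterior()] (e.g. `method`).
#' @return A `counselnet_posterior`.
#' @export
predict.counselnet <- function(object, query, evidence = list(), ...) {
  posterior(object, query, evidence, ...)
}

#' Forward-sample joint states from a counseling network
#'
#' Ancestral sampling in topological order; useful for approximate sanity
#' checks of exact posteriors.
#'
#' @param object A `counselnet`.
#' @param nsim Number of samples.
#' @param seed Optional seed (the caller's RNG state is preserved).
#' @param ... Unused.
#' @return A data frame with one column per node and `nsim` rows of state
#'   labels.
#' @export
simulate.counselnet <- function(object, nsim = 1, seed = NULL, ...) {
  ord <- topological_order(object)
  run <- function() {
    out <- vector("list", length(ord))
    names(out) <- ord
    for (nm in ord) {
      nd <- object$nodes[[nm]]
      if (!length(nd$parents)) {
        out[[nm]] <- sample(nd$states, nsim, replace = TRUE, prob = nd$cpt)
      } else {
        out[[nm]] <- vapply(seq_len(nsim), function(i) {
          idx <- c(list(TRUE), lapply(nd$parents, function(p) out[[p]][i]))
          p <- as.numeric(do.call(`[`, c(list(nd$cpt), idx)))
          sample(nd$states, 1L, prob = p)
        }, "")
      }
    }
    as.data.frame(out, stringsAsFactors = FALSE)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Plot the network DAG
#'
#' Draws the directed acyclic graph of the network (genotype, phenotype,
#' risk-factor and test nodes). Requires the igraph package.
#'
#' @param x A `counselnet`.
#' @param ... Passed to `plot.igraph`.
#' @return Invisibly, the igraph object.
#' @export
plot.counselnet <- function(x, ...) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("plotting the network DAG requires the igraph package")
  edges <- do.call(rbind, lapply(x$nodes, function(nd) {
    if (length(nd$parents)) cbind(nd$parents, nd$name) else NULL
  }))
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = names(x$nodes)))
  kind <- substr(names(x$nodes), 1, 1)
  cols <- c(G = "lightgoldenrod", P = "lightsteelblue", D = "grey90",
            E = "grey90", A = "grey90", "T" = "palegreen")
  igraph::plot.igraph(g, vertex.color = cols[kind],
                      vertex.label.cex = 0.8, edge.arrow.size = 0.4, ...)
  invisible(g)
}
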