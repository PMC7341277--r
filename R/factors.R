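# Internal discrete-factor algebra used by both inference routes.
#
# A factor is a numeric array whose dimnames are a *named* list: the names
# are variable (node) identifiers, the entries their state labels. A factor
# reduced on all of its variables degenerates to a bare scalar (no dim).

f_vars <- function(f) names(dimnames(f))

f_is_scalar <- function(f) is.null(dim(f))

# Extend `f` to the variable set `vars` (a superset of its own, in the
# requested order), replicating values over the new dimensions.
f_expand <- function(f, vars, states) {
  cur <- f_vars(f)
  add <- setdiff(vars, cur)
  if (length(add)) {
    f <- array(f, dim = c(dim(f), lengths(states[add])),
               dimnames = c(dimnames(f), states[add]))
  }
  aperm(f, match(vars, f_vars(f)))
}

f_product <- function(f1, f2, states) {
  if (f_is_scalar(f1)) return(f2 * as.numeric(f1))
  if (f_is_scalar(f2)) return(f1 * as.numeric(f2))
  vars <- union(f_vars(f1), f_vars(f2))
  f_expand(f1, vars, states) * f_expand(f2, vars, states)
}

# Sum a variable out of a factor; may return a scalar.
f_sum_out <- function(f, var) {
  vars <- f_vars(f)
  keep <- setdiff(vars, var)
  if (!length(keep)) return(sum(f))
  res <- apply(f, match(keep, vars), sum)
  if (length(keep) == 1L) {
    array(res, dim = length(res), dimnames = dimnames(f)[keep])
  } else {
    dimnames(res) <- dimnames(f)[keep]
    res
  }
}

# Slice a factor on observed states; observed dimensions are dropped.
f_reduce <- function(f, evidence) {
  vars <- f_vars(f)
  obs <- intersect(vars, names(evidence))
  if (!length(obs)) return(f)
  idx <- lapply(vars, function(v) if (v %in% obs) evidence[[v]] else TRUE)
  g <- do.call(`[`, c(list(f), idx, list(drop = FALSE)))
  keep <- setdiff(vars, obs)
  if (!length(keep)) return(as.numeric(g))
  array(g, dim = dim(f)[match(keep, vars)], dimnames = dimnames(f)[keep])
}
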