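#' Beta prior on a probability
#'
#' Leak and link probabilities of the noisy-OR gates are uncertain quantities
#' in (0, 1); a Beta distribution, conjugate to the Bernoulli, represents that
#' uncertainty with two shape parameters.
#'
#' @param alpha,beta Positive shape parameters.
#' @return An object of class `beta_spec`.
#' @seealso [beta_from_moments()], [beta_from_mean_concentration()]
#' @examples
#' b <- beta_spec(0.9, 8.1)
#' beta_mean(b)  # 0.10
#' beta_sd(b)    # ~0.0949
#' @export
beta_spec <- function(alpha, beta) {
  for (x in list(alpha, beta))
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      stop_validation("Beta shape parameters must be single positive finite numbers")
  structure(list(alpha = alpha, beta = beta), class = "beta_spec")
}

#' @export
print.beta_spec <- function(x, ...) {
  cat(sprintf("Beta(%.4g, %.4g)  mean = %.4g, sd = %.4g\n",
              x$alpha, x$beta, beta_mean(x), beta_sd(x)))
  invisible(x)
}

#' Mean and standard deviation of a prior
#'
#' A prior on a gate probability is either a `beta_spec` or a bare number
#' (a point mass, used for deterministic-limit scenarios).
#'
#' @param x A `beta_spec` or a single probability.
#' @return A single number.
#' @export
beta_mean <- function(x) {
  if (inherits(x, "beta_spec")) return(x$alpha / (x$alpha + x$beta))
  assert_probability(x, "point prior")
  x
}

#' @rdname beta_mean
#' @export
beta_sd <- function(x) {
  if (inherits(x, "beta_spec")) {
    a <- x$alpha; b <- x$beta
    return(sqrt(a * b / ((a + b)^2 * (a + b + 1))))
  }
  assert_probability(x, "point prior")
  0
}

#' Elicit a Beta prior from its mean and standard deviation
#'
#' Moment matching: with concentration \eqn{\nu = m(1-m)/s^2 - 1}, the shapes
#' are \eqn{\alpha = m\nu} and \eqn{\beta = (1-m)\nu}. The moments are only
#' feasible when \eqn{s^2 < m(1-m)}.
#'
#' @param mean Prior mean, strictly in (0, 1).
#' @param sd Prior standard deviation, positive.
#' @return A `beta_spec` whose analytic mean and sd equal the inputs.
#' @examples
#' beta_from_moments(0.10, 0.09487)  # ~Beta(0.9, 8.1)
#' @export
beta_from_moments <- function(mean, sd) {
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean) ||
      mean <= 0 || mean >= 1)
    stop_validation("mean must lie strictly in (0, 1)")
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd <= 0)
    stop_validation("sd must be a single positive finite number")
  if (sd^2 >= mean * (1 - mean))
    stop_validation("infeasible moments: sd^2 = %.4g >= mean*(1-mean) = %.4g",
                    sd^2, mean * (1 - mean))
  nu <- mean * (1 - mean) / sd^2 - 1
  beta_spec(mean * nu, (1 - mean) * nu)
}

#' Elicit a Beta prior from its mean and concentration
#'
#' When only a mean is stated, the prior is pinned down by a concentration
#' \eqn{\nu = \alpha + \beta}: \eqn{\alpha = m\nu}, \eqn{\beta = (1-m)\nu}.
#' The package default \eqn{\nu = 9} gives sd 9.49% at mean 10%.
#'
#' @param mean Prior mean, strictly in (0, 1).
#' @param nu Concentration (sum of the shapes), positive.
#' @return A `beta_spec`.
#' @export
beta_from_mean_concentration <- function(mean, nu) {
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean) ||
      mean <= 0 || mean >= 1)
    stop_validation("mean must lie strictly in (0, 1)")
  if (!is.numeric(nu) || length(nu) != 1L || !is.finite(nu) || nu <= 0)
    stop_validation("nu must be a single positive finite number")
  beta_spec(mean * nu, (1 - mean) * nu)
}

#' Draw from a prior
#'
#' @param x A `beta_spec` or a point probability.
#' @param n Number of draws (>= 1).
#' @param seed Optional integer seed; the caller's RNG state is left untouched.
#' @return Numeric vector of `n` values in (0, 1) (constant for a point prior).
#' @export
sample_prior <- function(x, n, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1)
    stop_validation("n must be a count >= 1")
  n <- as.integer(n)
  draw <- function() {
    if (inherits(x, "beta_spec")) stats::rbeta(n, x$alpha, x$beta)
    else rep(beta_mean(x), n)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Prior group for one gate parameterization
#'
#' Bundles the three priors a counseling scenario needs: the leak (background)
#' probability, one shared prior for the three non-genetic links (diet,
#' exercise, age), and the genetic link. Each component may be a [beta_spec()]
#' or a bare probability (a point mass).
#'
#' @param leak,link_ng,link_g Priors (`beta_spec` or probability).
#' @param label Optional identifier.
#' @return An object of class `prior_group`.
#' @export
prior_group <- function(leak, link_ng, link_g, label = NULL) {
  for (x in list(leak, link_ng, link_g))
    if (!inherits(x, "beta_spec")) assert_probability(x, "prior component")
  structure(list(leak = leak, link_ng = link_ng, link_g = link_g,
                 label = label), class = "prior_group")
}

#' @export
print.prior_group <- function(x, ...) {
  cat(sprintf("Prior group%s\n", if (is.null(x$label)) "" else paste0(" '", x$label, "'")))
  for (nm in c("leak", "link_ng", "link_g")) {
    p <- x[[nm]]
    cat(sprintf("  %-8s mean %6.2f%%  sd %6.2f%%%s\n", nm,
                100 * beta_mean(p), 100 * beta_sd(p),
                if (inherits(p, "beta_spec"))
                  sprintf("  [Beta(%.3g, %.3g)]", p$alpha, p$beta)
                else "  [point]"))
  }
  invisible(x)
}

#' The seven illustrative prior groups of the degenerative-myelopathy example
#'
#' Non-genetic link means of 10, 30 or 50% crossed with genetic link means of
#' 10, 50 or 90% (the genetic mean never below the non-genetic mean), leak
#' mean fixed at 1% throughout. All priors use the default concentration
#' \eqn{\nu = 9}, which reproduces the 9.49% sd at a 10% mean.
#'
#' @param nu Concentration applied to every prior (default 9).
#' @return A list of seven [prior_group()] objects, labelled `group1`..`group7`.
#' @export
dm_prior_groups <- function(nu = 9) {
  ng <- c(0.10, 0.30, 0.10, 0.30, 0.10, 0.30, 0.50)
  g  <- c(0.10, 0.10, 0.50, 0.50, 0.90, 0.90, 0.50)
  lapply(seq_len(7), function(k) {
    prior_group(leak    = beta_from_mean_concentration(0.01, nu),
                link_ng = beta_from_mean_concentration(ng[k], nu),
                link_g  = beta_from_mean_concentration(g[k], nu),
                label   = paste0("group", k))
  })
}

#' Monte Carlo summary of a noisy-OR risk under prior uncertainty
#'
#' Propagates the Beta priors through the leaky noisy-OR risk
#' \eqn{1 - (1-l)\prod_i(1-p_i)} for a given number of active non-genetic
#' causes and an optionally active genetic cause, reporting the Monte Carlo
#' mean and sd of the risk.
#'
#' In `draw_mode = "independent"` each active non-genetic cause gets its own
#' draw from the shared link prior (each cause a separate mechanism); in
#' `"shared_ng"` one draw is reused for all non-genetic causes within a
#' parameter realization. The two agree exactly when the priors are point
#' masses, and the independent-mode mean converges to the closed form
#' \eqn{1 - (1-m_0)\prod_i(1-m_i)} built from the prior means.
#'
#' @param group A [prior_group()].
#' @param n_ng_active Number of active non-genetic causes, 0..3.
#' @param g_active Logical; is the genetic cause active?
#' @param n_draws Number of Monte Carlo draws (>= 2).
#' @param seed Root integer seed, split internally per sampled quantity.
#' @param draw_mode `"independent"` or `"shared_ng"`.
#' @return Named numeric vector `c(mean = , sd = )`, on the probability scale.
#' @export
summarize_risk <- function(group, n_ng_active, g_active, n_draws = 10000,
                           seed = 1L, draw_mode = c("independent", "shared_ng")) {
  draw_mode <- match.arg(draw_mode)
  if (!inherits(group, "prior_group")) stop_validation("group must be a prior_group")
  if (!is.numeric(n_ng_active) || length(n_ng_active) != 1L ||
      !(n_ng_active %in% 0:3))
    stop_validation("n_ng_active must be 0, 1, 2 or 3")
  if (!is.numeric(n_draws) || length(n_draws) != 1L || n_draws < 2)
    stop_validation("n_draws must be >= 2")
  n_draws <- as.integer(n_draws)

  surv <- 1 - sample_prior(group$leak, n_draws, split_seed(seed, "leak"))
  if (n_ng_active > 0) {
    if (draw_mode == "independent") {
      for (j in seq_len(n_ng_active))
        surv <- surv * (1 - sample_prior(group$link_ng, n_draws,
                                         split_seed(seed, paste0("ng", j))))
    } else {
      p <- sample_prior(group$link_ng, n_draws, split_seed(seed, "ng_shared"))
      surv <- surv * (1 - p)^n_ng_active
    }
  }
  if (isTRUE(g_active))
    surv <- surv * (1 - sample_prior(group$link_g, n_draws, split_seed(seed, "g")))
  risk <- 1 - surv
  c(mean = mean(risk), sd = stats::sd(risk))
}

#' Risk table for a prior group
#'
#' Summarizes the risk of clinical signs for every standard cause combination:
#' one to three active non-genetic factors, with and without the genetic
#' cause. Values are fractions; multiply by 100 for percent.
#'
#' @inheritParams summarize_risk
#' @param include_baseline Also report the zero-active-cause rows `NG0`
#'   (risk = leak) and `NG0+G`.
#' @return A data frame with columns `risk`, `mean`, `sd`.
#' @export
risk_table <- function(group, n_draws = 10000, seed = 1L,
                       draw_mode = c("independent", "shared_ng"),
                       include_baseline = FALSE) {
  draw_mode <- match.arg(draw_mode)
  rows <- list(
    NG1 = c(1, FALSE), NG2 = c(2, FALSE), NG3 = c(3, FALSE),
    G = c(0, TRUE),
    `NG1+G` = c(1, TRUE), `NG2+G` = c(2, TRUE), `NG3+G` = c(3, TRUE))
  if (include_baseline)
    rows <- c(list(NG0 = c(0, FALSE)), rows)
  out <- t(vapply(rows, function(r) {
    summarize_risk(group, n_ng_active = r[1], g_active = as.logical(r[2]),
                   n_draws = n_draws, seed = seed, draw_mode = draw_mode)
  }, c(mean = 0, sd = 0)))
  data.frame(risk = rownames(out), mean = out[, "mean"], sd = out[, "sd"],
             row.names = NULL)
}
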