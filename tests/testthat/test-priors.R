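# Beta prior elicitation, sampling, and Monte Carlo risk summaries.

test_that("moment matching recovers the stated elicitation examples", {
  b <- beta_from_moments(0.10, 0.09487)
  expect_equal(b$alpha, 0.9, tolerance = 1e-3)
  expect_equal(b$beta, 8.1, tolerance = 1e-3)
  expect_equal(beta_mean(b), 0.10, tolerance = 1e-12)
  expect_equal(beta_sd(b), 0.09487, tolerance = 1e-12)

  u <- beta_from_moments(0.50, sqrt(1 / 12))
  expect_equal(u$alpha, 1, tolerance = 1e-9)
  expect_equal(u$beta, 1, tolerance = 1e-9)

  expect_error(beta_from_moments(0.10, 0.40), "infeasible moments",
               class = "cn_validation_error")
  expect_error(beta_from_moments(1.2, 0.1), class = "cn_validation_error")
  expect_error(beta_from_moments(0.5, Inf), class = "cn_validation_error")
})

test_that("mean + concentration elicitation is exact arithmetic", {
  b <- beta_from_mean_concentration(0.10, 9)
  expect_equal(c(b$alpha, b$beta), c(0.9, 8.1))
  expect_equal(unlist(beta_from_mean_concentration(0.5, 2)[c("alpha", "beta")]),
               c(alpha = 1, beta = 1))
  leak <- beta_from_mean_concentration(0.01, 9)
  expect_equal(c(leak$alpha, leak$beta), c(0.09, 8.91))
  expect_error(beta_from_mean_concentration(0, 9), class = "cn_validation_error")
})

test_that("moment round trip recovers the shape parameters", {
  for (ab in list(c(0.9, 8.1), c(1, 1), c(5, 2), c(0.09, 8.91), c(30, 70))) {
    spec <- beta_spec(ab[1], ab[2])
    back <- beta_from_moments(beta_mean(spec), beta_sd(spec))
    expect_equal(back$alpha, spec$alpha, tolerance = 1e-9)
    expect_equal(back$beta, spec$beta, tolerance = 1e-9)
  }
})

test_that("prior sampling is seed-deterministic and matches analytic moments", {
  u <- beta_spec(1, 1)
  expect_identical(sample_prior(u, 4, seed = 11), sample_prior(u, 4, seed = 11))
  expect_error(sample_prior(u, 0), class = "cn_validation_error")

  b <- beta_spec(0.9, 8.1)
  x <- sample_prior(b, 1e5, seed = 7)
  expect_true(all(x > 0 & x < 1))
  expect_lt(abs(mean(x) - 0.10), 4 * beta_sd(b) / sqrt(1e5))

  xu <- sample_prior(u, 1e5, seed = 7)
  expect_lt(abs(sd(xu) - sqrt(1 / 12)), 4 * sd(xu) / sqrt(2 * (1e5 - 1)))

  # point priors sample as constants
  expect_identical(sample_prior(0.25, 3, seed = 1), rep(0.25, 3))
})

test_that("risk summaries converge to the closed form and respect ordering", {
  g <- prior_group(leak = beta_from_mean_concentration(0.01, 9),
                   link_ng = beta_from_mean_concentration(0.10, 9),
                   link_g = beta_from_mean_concentration(0.90, 9))
  r <- summarize_risk(g, 2, FALSE, n_draws = 50000, seed = 3)
  closed <- 1 - 0.99 * 0.9 * 0.9
  expect_lt(abs(r[["mean"]] - closed), 4 * r[["sd"]] / sqrt(50000))

  # no active causes: the risk is the leak
  r0 <- summarize_risk(g, 0, FALSE, n_draws = 20000, seed = 5)
  expect_lt(abs(r0[["mean"]] - 0.01), 4 * r0[["sd"]] / sqrt(20000))

  # degenerate (point) priors: zero spread, exact point risk
  gp <- prior_group(0.01, 0.1, 0.9)
  rp <- summarize_risk(gp, 2, TRUE, n_draws = 100, seed = 1)
  expect_identical(rp[["sd"]], 0)
  expect_equal(rp[["mean"]], 1 - 0.99 * 0.9 * 0.9 * 0.1, tolerance = 1e-15)

  # shared and independent modes agree exactly for degenerate priors
  expect_identical(summarize_risk(gp, 3, FALSE, 100, 1, "shared_ng"),
                   summarize_risk(gp, 3, FALSE, 100, 1, "independent"))
  expect_error(summarize_risk(g, 5, FALSE), class = "cn_validation_error")
})

test_that("risk means are monotone in active causes for all packaged groups", {
  for (g in dm_prior_groups()) {
    tab <- risk_table(g, n_draws = 10000, seed = 9)
    m <- setNames(tab$mean, tab$risk)
    expect_lt(m[["NG1"]], m[["NG2"]])
    expect_lt(m[["NG2"]], m[["NG3"]])
    for (x in c("NG1", "NG2", "NG3"))
      expect_gt(m[[paste0(x, "+G")]], m[[x]])
  }
})
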