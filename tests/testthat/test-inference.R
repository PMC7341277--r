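# Exact inference: enumeration oracle, variable elimination, named queries.

test_that("enumeration mass equals the evidence probability", {
  net <- build_trio(prior_group(0.01, 0.1, 0.9))
  expect_equal(joint_enumeration(net, list())$mass, 1, tolerance = 1e-12)
  # P(offspring BB) under uniform founders: mean transmission over 9 pairs
  expect_equal(joint_enumeration(net, list(G_offsp = "BB"))$mass, 0.25,
               tolerance = 1e-12)
  expect_error(joint_enumeration(net, list(G_sire = "AA", G_offsp = "BB")),
               "inconsistent evidence", class = "cn_validation_error")
})

test_that("backward query: parent genotype given a BB-tested offspring", {
  net <- build_trio(prior_group(0.01, 0.1, 0.9))
  p <- posterior(net, "G_sire", list(G_offsp = "BB"))
  expect_equal(p$prob, c(AA = 0, AB = 1/3, BB = 2/3), tolerance = 1e-12)
})

test_that("deterministic-limit closed forms are reproduced exactly", {
  net <- deterministic_trio()
  expect_equal(posterior(net, "G_offsp", healthy_parents_evidence())$prob,
               c(AA = 0.5625, AB = 0.375, BB = 0.0625), tolerance = 1e-12)
  expect_equal(posterior(net, "G_offsp", dam_signs_evidence())$prob,
               c(AA = 0, AB = 0.5, BB = 0.5), tolerance = 1e-12)
})

test_that("allele-frequency founder priors drive the offspring BB posterior", {
  for (q in c(0.5, 0.1)) {
    net <- deterministic_trio(sire_prior = sprintf("hwe(%g)", q))
    p <- posterior(net, "G_offsp", dam_signs_evidence())
    expect_equal(p$prob[["BB"]], q, tolerance = 1e-12)
  }
})

test_that("posterior validates queries and evidence", {
  net <- build_trio(prior_group(0.01, 0.1, 0.9))
  expect_error(posterior(net, "G_nope", list()), class = "cn_validation_error")
  expect_error(posterior(net, "G_sire", list(G_sire = "AA")),
               "already observed", class = "cn_validation_error")
  expect_error(posterior(net, "G_sire", list(G_dam = "XX")),
               "invalid state", class = "cn_validation_error")
  expect_error(posterior(net, "G_sire", list(Q_zz = "T")),
               "unknown node", class = "cn_validation_error")
})

test_that("counsel_risk equals the gate risk under certain genotype evidence", {
  net <- build_trio(prior_group(0.01, 0.1, 0.9))
  ng_false <- list(D_offsp = "F", E_offsp = "F", A_offsp = "F")
  expect_equal(counsel_risk(net, "offsp", c(list(G_offsp = "BB"), ng_false)),
               0.901, tolerance = 1e-12)
  expect_equal(counsel_risk(net, "offsp", c(list(G_offsp = "AA"), ng_false)),
               0.01, tolerance = 1e-12)
  # monotone in the number of active non-genetic factors, for every group
  for (g in dm_prior_groups()[c(1, 4, 7)]) {
    net_g <- build_trio(g)
    risks <- vapply(0:3, function(k) {
      st <- c("T", "T", "T", "F", "F", "F")[(4 - k):(6 - k)]
      counsel_risk(net_g, "offsp",
                   list(G_offsp = "BB", D_offsp = st[1], E_offsp = st[2],
                        A_offsp = st[3]))
    }, 0)
    expect_true(all(diff(risks) > 0))
  }
})

test_that("variable elimination agrees with enumeration on random scenarios", {
  for (s in 1:150) {
    sc <- random_scenario(s, n_individuals = 3 + s %% 3)
    p1 <- posterior(sc$net, sc$query, sc$evidence, method = "ve")
    p2 <- posterior(sc$net, sc$query, sc$evidence, method = "enumeration")
    expect_lt(max(abs(p1$prob - p2$prob)), 1e-10)
    expect_equal(p1$mass, p2$mass, tolerance = 1e-10)
  }
})

test_that("simulated joint frequencies approach exact posteriors", {
  net <- deterministic_trio()
  sims <- simulate(net, nsim = 20000, seed = 8)
  # P(offspring BB | dam BB): forward frequency vs exact inference
  sel <- sims$G_dam == "BB"
  freq <- mean(sims$G_offsp[sel] == "BB")
  exact <- posterior(net, "G_offsp", list(G_dam = "BB"))$prob[["BB"]]
  expect_lt(abs(freq - exact), 4 * sqrt(exact * (1 - exact) / sum(sel)))
})

test_that("parameter-draw-averaged posteriors are deterministic and coherent", {
  g5 <- dm_prior_groups()[[5]]
  ev_true <- list(P_dam = "T", D_dam = "T", E_dam = "T", A_dam = "T")
  ev_false <- dam_signs_evidence()
  r_true <- posterior_over_draws(g5, "G_offsp", ev_true, n_draws = 150, seed = 6)
  r_false <- posterior_over_draws(g5, "G_offsp", ev_false, n_draws = 150, seed = 6)
  # more active maternal non-genetic factors explain the signs away:
  # the BB posterior of the offspring drops
  expect_lt(r_true$mean[["BB"]], r_false$mean[["BB"]])
  expect_identical(r_true,
                   posterior_over_draws(g5, "G_offsp", ev_true, n_draws = 150,
                                        seed = 6))
  # degenerate priors: zero spread, mean equals the point-mean posterior
  pg <- prior_group(0.01, 0.1, 0.9)
  rd <- posterior_over_draws(pg, "G_offsp", ev_false, n_draws = 5, seed = 2)
  expect_true(all(rd$sd == 0))
  expect_equal(rd$mean,
               posterior(build_trio(pg), "G_offsp", ev_false)$prob,
               tolerance = 1e-12)
})
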