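# Network assembly: trio structure, CPT correctness, relatives, test nodes.

test_that("trio phenotype CPT rows follow the gate formula", {
  net <- build_trio(prior_group(0.01, 0.1, 0.9))  # point means of a 1/10/90 group
  cpt <- net$nodes$P_offsp$cpt
  # BB, no non-genetic factors: 1 - 0.99 * 0.1
  expect_equal(cpt["T", "BB", "F", "F", "F"], 1 - 0.99 * 0.1, tolerance = 1e-15)
  expect_equal(cpt["T", "BB", "F", "F", "F"], 0.901, tolerance = 1e-12)
  # recessive model: AA and AB rows identical for any factor states
  expect_identical(cpt[, "AA", , , ], cpt[, "AB", , , ])
  # all-false non-genetic, AA: only the leak
  expect_identical(cpt["T", "AA", "F", "F", "F"], 0.01)
})

test_that("every CPT row of a constructed network sums to one", {
  net <- build_trio(dm_prior_groups()[[3]], cpt_mode = "mc_mean", draws = 500,
                    seed = 4)
  net <- add_test_node(net, "offsp", 0.98, 0.95)
  for (nd in net$nodes) {
    tot <- if (length(dim(nd$cpt)) == 1L) sum(nd$cpt)
           else apply(nd$cpt, seq_along(dim(nd$cpt))[-1L], sum)
    expect_true(all(abs(tot - 1) < 1e-12))
  }
})

test_that("mc_mean gates equal point_mean gates when priors are degenerate", {
  pg <- prior_group(0.02, 0.3, 0.8)
  n1 <- build_trio(pg, cpt_mode = "point_mean")
  n2 <- build_trio(pg, cpt_mode = "mc_mean", draws = 64, seed = 10)
  for (nm in names(n1$nodes))
    expect_identical(n1$nodes[[nm]]$cpt, n2$nodes[[nm]]$cpt)
})

test_that("network structure audit: one genotype, phenotype and three factors each", {
  net <- build_trio(prior_group(0.01, 0.1, 0.9))
  net <- add_relative(net, "mate")
  net <- add_relative(net, "pup2", sire = "offsp", dam = "mate")
  aud <- counselnet:::network_audit(net)
  expect_equal(nrow(aud), 5)
  expect_true(all(aud$genotype) && all(aud$phenotype))
  expect_true(all(aud$n_risk_factors == 3))
  expect_equal(length(net$nodes), 5 * 5)
})

test_that("adding a barren relative leaves trio posteriors unchanged", {
  net <- build_trio(prior_group(0.01, 0.1, 0.9))
  p0 <- posterior(net, "G_sire", list(G_offsp = "BB"))$prob
  net2 <- add_relative(net, "mate")
  net2 <- add_relative(net2, "pup2", sire = "offsp", dam = "mate")
  p1 <- posterior(net2, "G_sire", list(G_offsp = "BB"))$prob
  expect_equal(p1, p0, tolerance = 1e-12)
})

test_that("pedigree structure errors are explicit", {
  net <- build_trio(prior_group(0.01, 0.1, 0.9))
  expect_error(add_relative(net, "offsp"), "duplicate",
               class = "cn_validation_error")
  expect_error(add_relative(net, "x", sire = "x", dam = "dam"),
               "unknown parent", class = "cn_validation_error")
  expect_error(add_relative(net, "x", sire = "sire"),
               class = "cn_validation_error")
  expect_error(add_relative(net, "x", sire = "dam", dam = "dam"),
               "distinct", class = "cn_validation_error")
})

test_that("a descendant chain of depth three still normalizes", {
  net <- build_trio(prior_group(0, 0.1, 1))
  net <- add_relative(net, "mate1")
  # four individuals: with all 12 risk factors pinned, the evidence mass is
  # exactly the product of their 0.5 root priors
  rf <- setNames(as.list(rep("F", 12)),
                 paste0(rep(c("D", "E", "A"), 4), "_",
                        rep(c("sire", "dam", "offsp", "mate1"), each = 3)))
  expect_equal(joint_enumeration(net, rf)$mass, 0.5^12, tolerance = 1e-12)
  net <- add_relative(net, "gen2", sire = "offsp", dam = "mate1")
  net <- add_relative(net, "mate2")
  net <- add_relative(net, "gen3", sire = "gen2", dam = "mate2")
  p <- posterior(net, "G_gen2", list(G_sire = "BB", G_dam = "BB", G_mate1 = "AA"))
  expect_equal(p$prob, c(AA = 0, AB = 1, BB = 0), tolerance = 1e-12)
  # grand-offspring of certain BB x BB through an AA mate carries one B allele
  p3 <- posterior(net, "G_gen3",
                  list(G_sire = "BB", G_dam = "BB", G_mate1 = "AA", G_mate2 = "AA"))
  expect_equal(p3$prob, c(AA = 0.5, AB = 0.5, BB = 0), tolerance = 1e-12)
})

test_that("swapping sire and dam evidence leaves offspring posteriors unchanged", {
  net <- build_trio(dm_prior_groups()[[5]])
  ev1 <- list(P_sire = "T", D_sire = "T", E_sire = "F", A_sire = "F",
              P_dam = "F", D_dam = "F", E_dam = "F", A_dam = "T")
  swap <- function(e) {
    nm <- names(e)
    nm <- sub("_sire$", "_tmp", nm)
    nm <- sub("_dam$", "_sire", nm)
    nm <- sub("_tmp$", "_dam", nm)
    setNames(e, nm)
  }
  p1 <- posterior(net, "G_offsp", ev1)$prob
  p2 <- posterior(net, "G_offsp", swap(ev1))$prob
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("test nodes encode sensitivity/specificity with explicit AB semantics", {
  base <- build_trio(prior_group(0.01, 0.1, 0.9))
  perfect <- add_test_node(base, "offsp", 1, 1)
  p <- posterior(perfect, "G_offsp", list(T_offsp = "pos"))$prob
  expect_equal(p, c(AA = 0, AB = 0, BB = 1), tolerance = 1e-12)

  # uninformative test: posteriors equal priors, and evidence on the barren
  # leaf never perturbs other posteriors
  flat <- add_test_node(base, "offsp", 0.5, 0.5)
  expect_equal(posterior(flat, "G_offsp", list(T_offsp = "pos"))$prob,
               posterior(flat, "G_offsp", list())$prob, tolerance = 1e-12)
  expect_equal(posterior(flat, "G_sire", list(T_offsp = "neg"))$prob,
               posterior(base, "G_sire", list())$prob, tolerance = 1e-12)

  # perfect allele-detection test: a positive offspring rules out AA x AA
  allele <- add_test_node(base, "offsp", 1, 1, semantics = "detect_allele")
  expect_error(
    joint_enumeration(allele, list(T_offsp = "pos", G_sire = "AA", G_dam = "AA")),
    "inconsistent evidence", class = "cn_validation_error")

  expect_error(add_test_node(base, "nobody", 1, 1), class = "cn_validation_error")
  expect_error(add_test_node(base, "offsp", 1.2, 1), class = "cn_validation_error")
})
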