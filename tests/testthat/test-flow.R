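test_that("uptake matrix splits metabolites by abundance times rate", {
  ia <- data.frame(species = c("A", "B"), metabolite = "m1",
                   direction = "consumption")
  net <- cross_feeding_network(ia)

  # single consumer: normalization forces 1
  s1 <- community_sample("s", c(A = 1))
  A1 <- build_uptake_matrix(
    cross_feeding_network(ia[1, , drop = FALSE]), s1)
  expect_equal(unname(A1["A", "m1"]), 1)

  # two consumers split by abundance
  s2 <- community_sample("s", c(A = 0.75, B = 0.25))
  A2 <- build_uptake_matrix(net, s2)
  expect_equal(unname(A2[, "m1"]), c(0.75, 0.25))

  # rates weight the split: (lambda, B) = (2, .5), (1, .5) -> 2/3, 1/3
  s3 <- community_sample("s", c(A = 0.5, B = 0.5))
  p3 <- flow_parameters(uptake_rates = data.frame(
    species = "A", metabolite = "m1", rate = 2))
  A3 <- build_uptake_matrix(net, s3, p3)
  expect_equal(unname(A3[, "m1"]), c(2, 1) / 3)

  # consumed only by a zero-abundance species -> all-zero column, flagged
  s4 <- community_sample("s", c(A = 0, B = 1))
  net4 <- cross_feeding_network(
    data.frame(species = c("A", "B"), metabolite = c("m1", "m2"),
               direction = "consumption"))
  A4 <- build_uptake_matrix(net4, s4)
  expect_equal(sum(A4[, "m1"]), 0)
  expect_false(attr(A4, "consumable")[["m1"]])
  expect_true(attr(A4, "consumable")[["m2"]])
})

test_that("secretion matrix equal-splits byproducts and flags sink species", {
  ia <- rbind(
    data.frame(species = "A", metabolite = paste0("m", 1:4),
               direction = "production"),
    data.frame(species = "B", metabolite = "m1", direction = "production"),
    data.frame(species = "C", metabolite = "m1", direction = "consumption")
  )
  net <- cross_feeding_network(ia)
  A <- build_secretion_matrix(net)
  expect_equal(unname(A[paste0("m", 1:4), "A"]), rep(0.25, 4))
  expect_equal(unname(A["m1", "B"]), 1)
  expect_equal(sum(A[, "C"]), 0)          # no byproducts -> zero column
  expect_true(attr(A, "has_sink")[["C"]])

  # explicit weights are renormalized per species; negatives rejected
  expect_error(
    flow_parameters(secretion_mode = "explicit",
                    secretion_weights = data.frame(
                      species = "A", metabolite = "m1", weight = -1)),
    "non-negative")
  pw <- flow_parameters(secretion_mode = "explicit",
                        secretion_weights = data.frame(
                          species = c("A", "A", "A", "A", "B"),
                          metabolite = c("m1", "m2", "m3", "m4", "m1"),
                          weight = c(2, 1, 1, 0, 3)))
  Aw <- build_secretion_matrix(net, pw)
  expect_equal(unname(Aw[paste0("m", 1:4), "A"]), c(0.5, 0.25, 0.25, 0))
  expect_equal(unname(Aw["m1", "B"]), 1)
})

test_that("chain cascade reproduces the hand-traced mass flow", {
  net <- chain_net()
  s <- community_sample("x", c(A = 0.5, B = 0.5))
  fl <- run_cascade(net, s, c(m0 = 1), flow_parameters(f = 0.9, n_levels = 2))
  expect_equal(unname(fl$biomass[c("A", "B")]), c(0.1, 0.09))
  expect_equal(unname(fl$metabolome[["m2"]]), 0.81)
  expect_equal(mass_balance_residual(fl), 0, tolerance = 1e-12)

  sm <- flow_summary(fl)
  expect_equal(sm$biomass_fraction, c(0.10, 0.09))
  expect_equal(sum(fl$metabolome) / sum(fl$intake), 0.81)
  expect_equal(sm$figure_level, sm$level + 1L)
})

test_that("single consumer converts 1 - f to biomass, f to metabolome", {
  ia <- data.frame(species = c("A", "A"), metabolite = c("m0", "m1"),
                   direction = c("consumption", "production"))
  net <- cross_feeding_network(ia)
  s <- community_sample("x", c(A = 1))
  for (N in c(1L, 3L, 7L)) {
    fl <- run_cascade(net, s, c(m0 = 1),
                      flow_parameters(f = 0.9, n_levels = N))
    expect_equal(sum(fl$biomass), 0.1)
    expect_equal(sum(fl$metabolome), 0.9)
  }
})

test_that("fully-consumable networks give the geometric closed form 1 - f^N", {
  net <- complete_net(3, 2)
  s <- community_sample("y", c(S1 = 0.2, S2 = 0.3, S3 = 0.5))
  fl <- run_cascade(net, s, c(m1 = 0.4, m2 = 0.6),
                    flow_parameters(f = 0.9, n_levels = 4))
  expect_equal(sum(fl$biomass), 1 - 0.9^4, tolerance = 1e-12)
  expect_equal(flow_summary(fl)$biomass_fraction,
               0.1 * 0.9^(0:3), tolerance = 1e-12)

  set.seed(42)
  for (k in 1:20) {
    f <- runif(1, 0.11, 0.98); N <- sample(1:10, 1)
    fl <- run_cascade(net, s, c(m1 = runif(1, 0.1, 2), m2 = runif(1, 0.1, 2)),
                      flow_parameters(f = f, n_levels = N))
    expect_equal(sum(fl$biomass) / sum(fl$intake), 1 - f^N,
                 tolerance = 1e-12)
  }
})

test_that("mass is conserved on random instances", {
  for (seed in 1:50) {
    inst <- random_instance(seed)
    fl <- run_cascade(inst$net, inst$sample, inst$intake, inst$params)
    expect_lt(mass_balance_residual(fl), 1e-9)
    expect_true(all(fl$biomass >= 0))
    expect_true(all(fl$metabolome >= 0))
    expect_true(all(fl$sink_by_level >= 0))
  }
})

test_that("recursion equals the matrix-power closed form on no-sink networks", {
  for (seed in 1:20) {
    inst <- random_instance(seed + 300, no_sink = TRUE)
    fl <- run_cascade(inst$net, inst$sample, inst$intake, inst$params)
    ora <- oracle_biomass(inst$net, inst$sample, inst$intake, inst$params)
    scale <- max(ora, 1e-30)
    expect_lt(max(abs(fl$biomass[names(ora)] - ora)) / scale, 1e-10)
  }
})

test_that("unconsumable parts satisfy A_in u = 0 exactly at every level", {
  for (seed in 1:10) {
    inst <- random_instance(seed + 600)
    fl <- run_cascade(inst$net, inst$sample, inst$intake, inst$params)
    Ain <- build_uptake_matrix(inst$net, inst$sample, inst$params,
                               metabolites = fl$metabolites)
    for (l in seq_len(fl$n_levels)) {
      expect_identical(max(abs(Ain %*% fl$unconsumable[, l])), 0)
      # entering pool splits exactly into consumable + unconsumable
      expect_true(all(fl$entering[, l] >= fl$unconsumable[, l]))
    }
  }
})

test_that("profiles are scale invariant and biomass non-decreasing in levels", {
  inst <- random_instance(77)
  fl1 <- run_cascade(inst$net, inst$sample, inst$intake, inst$params)
  fl2 <- run_cascade(inst$net, inst$sample, 3.7 * inst$intake, inst$params)
  p1 <- predict_profiles(fl1); p2 <- predict_profiles(fl2)
  expect_equal(p1$abundance, p2$abundance, tolerance = 1e-12)
  expect_equal(p1$metabolome, p2$metabolome, tolerance = 1e-12)

  prev <- -Inf
  for (N in 1:8) {
    fl <- run_cascade(inst$net, inst$sample, inst$intake,
                      flow_parameters(f = inst$params$f, n_levels = N))
    expect_gte(sum(fl$biomass), prev - 1e-12)
    prev <- sum(fl$biomass)
  }
})

test_that("intake metabolites unknown to the network pass through to the metabolome", {
  net <- chain_net()
  s <- community_sample("x", c(A = 1, B = 0))
  fl <- run_cascade(net, s, c(m0 = 0.5, exotic = 0.5),
                    flow_parameters(f = 0.9, n_levels = 2))
  expect_equal(unname(fl$metabolome[["exotic"]]), 0.5)
  expect_equal(unname(fl$unconsumable["exotic", 1]), 0.5)
  expect_lt(mass_balance_residual(fl), 1e-12)
})

test_that("degenerate inputs error clearly", {
  net <- chain_net()
  s <- community_sample("x", c(A = 1))
  expect_error(run_cascade(net, s, c(m0 = 0)), "all zero")
  expect_error(community_sample("x", c(A = 0)), "positive")
  expect_error(flow_parameters(f = 1.2), "f")
  expect_error(flow_parameters(n_levels = 0), "n_levels")
  expect_error(
    build_uptake_matrix(net, community_sample("x", c(Zeta = 1))),
    "not in network")
})

test_that("byproduct-free consumption routes f-fraction to the sink", {
  ia <- data.frame(species = "A", metabolite = "m0", direction = "consumption")
  net <- cross_feeding_network(ia)
  s <- community_sample("x", c(A = 1))
  fl <- run_cascade(net, s, c(m0 = 1), flow_parameters(f = 0.9, n_levels = 3))
  expect_equal(sum(fl$biomass), 0.1)
  expect_equal(sum(fl$sink_by_level), 0.9)
  expect_equal(sum(fl$metabolome), 0)
  expect_lt(mass_balance_residual(fl), 1e-12)
})

test_that("flow exports carry consistent totals", {
  net <- chain_net()
  s <- community_sample("x", c(A = 0.5, B = 0.5))
  params <- flow_parameters(f = 0.9, n_levels = 2)
  fl <- run_cascade(net, s, c(m0 = 1), params)
  long <- flow_long(fl)
  expect_equal(sum(long$amount[long$quantity == "biomass"]), sum(fl$biomass))
  edges <- flow_layer_edges(fl, net, s, params)
  # consumption flow into level 1 equals the consumable intake
  expect_equal(sum(edges$flow[edges$level == 1 & edges$kind == "consumption"]),
               1)
  expect_true(all(edges$flow > 0))
})

test_that("intake response collapses the cascade exactly", {
  inst <- random_instance(123)
  ints <- names(inst$intake)
  resp <- intake_response(inst$net, inst$sample, inst$params, ints)
  fl <- run_cascade(inst$net, inst$sample, inst$intake, inst$params)
  expect_equal(drop(resp$biomass %*% inst$intake[ints]), fl$biomass,
               tolerance = 1e-14)
  expect_equal(drop(resp$metabolome %*% inst$intake[ints]),
               fl$metabolome[rownames(resp$metabolome)], tolerance = 1e-14)
  expect_equal(sum(resp$sink * inst$intake[ints]), sum(fl$sink_by_level),
               tolerance = 1e-12)
})
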