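# Isotopomer mapping matrices, reversibility expansion, initial labeling
# states and the forward labeling simulation.

comp_net <- load_network(cho_network_path("compartmented"))

test_that("identity transport gives a permutation (identity) matrix", {
  net <- load_network(write_net(c(
    "name idt", "met A 2 cytosolic balanced", "met B 2 cytosolic balanced",
    "met S_ex 2 extracellular dynamic",
    "rxn upt: S_ex (ab) -> A (ab)", "rxn tr: A (ab) -> B (ab)")))
  tm <- build_mapping_matrices(net$reactions$tr, net$metabolites)
  expect_length(tm, 1L)
  expect_equal(tm[[1]]$M, diag(4))
})

test_that("cleavage routes pure labeling to pure products", {
  net <- load_network(write_net(c(
    "name clv", "met A 3 cytosolic balanced", "met B 2 cytosolic balanced",
    "met C 1 cytosolic balanced",
    "rxn cut: A (abc) -> B (ab) + C (c)")))
  tms <- build_mapping_matrices(net$reactions$cut, net$metabolites)
  idv_A <- c(rep(0, 7), 1)      # fully labeled (state 111)
  prods <- setNames(lapply(tms, function(t) as.numeric(t$M %*% idv_A)),
                    vapply(tms, function(t) t$product, ""))
  expect_equal(prods$B, c(0, 0, 0, 1))  # pure 11
  expect_equal(prods$C, c(0, 1))        # pure 1
})

test_that("IMM propagation equals brute-force enumeration on fixture reactions", {
  set.seed(5)
  for (which in c("compartmented", "noncompartmented")) {
    net <- load_network(cho_network_path(which))
    for (r in net$reactions) {
      has_map <- any(vapply(r$substrates, function(s) !is.null(s$map), TRUE))
      subs <- Filter(function(s) !is.null(s$map), r$substrates)
      if (!length(subs) &&
          !any(vapply(r$products, function(p) !is.null(p$map), TRUE))) next
      ns <- vapply(subs, function(s) net$metabolites[[s$id]]$n_carbons, 0L)
      if (prod(2^ns) > 4096) next   # joint enumeration cap
      idvs <- lapply(ns, function(n) { x <- runif(2^n); x / sum(x) })
      tms <- build_mapping_matrices(r, net$metabolites)
      prods <- Filter(function(p) !is.null(p$map), r$products)
      kept <- which(vapply(prods, function(p)
        !net$metabolites[[p$id]]$role %in% c("sink", "gas"), TRUE))
      expect_length(tms, length(kept))
      for (j in seq_along(kept)) {
        tm <- tms[[j]]
        oracle <- brute_force_product_idv(r, net$metabolites, idvs, kept[j])
        u <- if (!length(tm$inputs)) 1 else {
          ii <- match(tm$inputs, vapply(subs, function(s) s$id, ""))
          # kron with first input fastest, matching the term layout
          if (length(ii) == 1L) idvs[[ii[1]]]
          else as.numeric(outer(idvs[[ii[1]]], idvs[[ii[2]]]))
        }
        expect_equal(as.numeric(tm$M %*% u), oracle, tolerance = 1e-12,
                     info = paste(which, r$id, tm$product))
      }
    }
  }
})

test_that("the lumped oxPPP transfers carbon exactly (3 G6P -> 5 PG + 3 CO2)", {
  r <- comp_net$reactions$ppp
  set.seed(6)
  idvs <- lapply(1:3, function(i) { x <- runif(64); x / sum(x) })
  tms <- build_mapping_matrices(r, comp_net$metabolites)
  # five PG instances at weight 1/3 each plus three CO2 instances
  expect_identical(sum(vapply(tms, function(t) t$product == "PG_c", TRUE)), 5L)
  expect_identical(sum(vapply(tms, function(t) t$product == "CO2", TRUE)), 3L)
  expect_true(all(abs(vapply(tms, function(t) t$w, 0) - 1 / 3) < 1e-12))
  # column-stochastic: every mapping matrix conserves probability mass
  for (tm in tms) expect_equal(colSums(tm$M), rep(1, ncol(tm$M)))
})

test_that("reversibility expansion follows the exchange-flux definition", {
  models <- list(r1 = NULL,
                 r2 = list(kind = "constant", rev = 0),
                 r3 = list(kind = "constant", rev = 1),
                 r4 = list(kind = "exponential", alpha = 0.154, beta = 0.0359),
                 r5 = list(kind = "constant", rev = 0.5))
  v <- c(r1 = 5, r2 = 10, r3 = 10, r4 = 10, r5 = -4)
  ex <- expand_reversibilities(v, models, t = 0)
  expect_equal(ex$fwd, c(5, 10, 20, 10 * 1.154, 0.5 * 4))
  expect_equal(ex$rev, c(0, 0, 10, 10 * 0.154, 4 + 2))
  # net = fwd - rev in the written direction
  expect_equal(ex$fwd - ex$rev, unname(v))

  ex48 <- expand_reversibilities(c(r4 = 10), models["r4"], t = 48)
  expect_equal(ex48$rev, 10 * 0.154 * exp(0.0359 * 48))

  expect_error(expand_reversibilities(c(r1 = -1), models["r1"]), "negative")
  expect_error(rev_value(list(kind = "exponential", alpha = -1, beta = 0), 1),
               "negative")
})

test_that("hyperbolic and exponential reversibility models evaluate correctly", {
  hyp <- list(kind = "hyperbolic", rev0 = 2700, eps = 0.01)
  expect_equal(rev_value(hyp, 0), 270000)
  expect_equal(rev_value(hyp, 1), 2700 / 1.01)
  expf <- list(kind = "exponential", alpha = 0.154, beta = 0.0359)
  expect_equal(rev_value(expf, 0), 0.154)
})

test_that("initial IDVs encode tracer purity and natural abundance", {
  idvs <- initial_idvs(comp_net, tracer_spec("GLC_ex", 0.99, 0.011))
  # unlabeled 3-carbon pool: M+0 = 0.989^3
  mid <- idv_to_mid(idvs$PYR_c1)
  expect_equal(mid[1], 0.989^3, tolerance = 1e-12)
  # tracer: fully labeled isotopomer fraction 0.99^6
  expect_equal(idvs$GLC_ex[64], 0.99^6, tolerance = 1e-12)
  # zero-carbon rule
  expect_equal(bernoulli_idv(0, 0.5), 1)
})

test_that("extracellular pools with no influx keep a constant IDV", {
  # all fluxes zero: the exported pool's labeling never moves
  net <- load_network(toy_branch_net(upt = 0, rev = 0))
  ff <- extract_free_fluxes(net)
  v <- ff$solver(c(dil = 0))
  sim <- simulate_labeling(net, v, experiment = toy_experiment(),
                           fragments = toy_fragments())
  nat <- idv_to_mid(bernoulli_idv(2, 0.011))
  for (ti in seq_along(sim$times))
    expect_equal(unname(sim$mids$P[ti, ]), nat, tolerance = 1e-9)
})

test_that("single-pool export matches the closed-form batch solution", {
  # with a fast intracellular pool and irreversible export, the
  # extracellular isotopomer balance integrates to
  #   MID(t) = L + (MID(0) - L) * C(0) / C(t)
  net <- load_network(toy_branch_net(upt = 100, rev = 0))
  ff <- extract_free_fluxes(net)
  v <- ff$solver(c(dil = 0))
  exp_des <- toy_experiment()
  sim <- simulate_labeling(net, v, experiment = exp_des,
                           fragments = toy_fragments(),
                           pool_sizes = c(A = 1e-3))
  L <- idv_to_mid(bernoulli_idv(2, 0.99))
  mid0 <- idv_to_mid(bernoulli_idv(2, 0.011))
  Xc0 <- cell_volume_concentration(4e5)
  Ct <- instcho:::conc_profile(sim$times, 5, 100, 0.0401, Xc0)
  for (ti in seq_along(sim$times)) {
    analytic <- L + (mid0 - L) * 5 / Ct[ti]
    expect_equal(unname(sim$mids$P[ti, ]), analytic, tolerance = 2e-3)
  }
})

test_that("simulated MIDs stay on the simplex for random feasible fluxes", {
  ff <- extract_free_fluxes(comp_net)
  set.seed(8)
  truth <- cho_truth_free()
  for (i in 1:3) {
    free <- truth * runif(length(truth), 0.7, 1.3)
    v <- ff$solver(free)
    if (!isTRUE(suppressWarnings(check_flux_vector(comp_net, v)))) next
    sim <- simulate_labeling(comp_net, v)
    for (m in sim$mids) {
      expect_true(all(m > -1e-6))
      expect_lt(max(abs(rowSums(m) - 1)), 1e-6)
    }
  }
})

test_that("an unlabeled tracer leaves every MID at natural abundance", {
  ff <- extract_free_fluxes(comp_net)
  v <- ff$solver(cho_truth_free())
  exp_nat <- default_experiment()
  exp_nat$tracer <- tracer_spec("GLC_ex", 0.011, 0.011)
  sim <- simulate_labeling(comp_net, v, experiment = exp_nat)
  frags <- default_fragments()
  for (k in seq_len(nrow(frags))) {
    nat <- idv_to_mid(bernoulli_idv(frags$n_backbone[k], 0.011))
    m <- sim$mids[[frags$fragment[k]]]
    for (ti in seq_len(nrow(m)))
      expect_equal(unname(m[ti, ]), nat, tolerance = 1e-6)
  }
})

test_that("halving the fast intracellular pools barely moves the MIDs", {
  ff <- extract_free_fluxes(comp_net)
  v <- ff$solver(cho_truth_free())
  sim1 <- simulate_labeling(comp_net, v)
  half <- default_pool_sizes(comp_net) / 2
  sim2 <- simulate_labeling(comp_net, v, pool_sizes = half)
  for (fr in names(sim1$mids))
    expect_lt(max(abs(sim1$mids[[fr]] - sim2$mids[[fr]])), 0.005)
})

test_that("depleting substrates truncate the simulation with a time stamp", {
  ff <- extract_free_fluxes(comp_net)
  v <- ff$solver(cho_truth_free())
  exp_short <- default_experiment()
  exp_short$C0["GLN_ex"] <- 4.0    # runs out near 56 h
  expect_error(simulate_labeling(comp_net, v, experiment = exp_short),
               "depleted at t")
})
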