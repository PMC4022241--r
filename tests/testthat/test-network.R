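# Network parsing, stoichiometry and free-flux extraction.

test_that("bundled fixtures parse with the published dimensions", {
  net <- load_network(cho_network_path("compartmented"))
  expect_length(net$reactions, 60L)
  expect_length(balanced <- rownames(build_stoichiometry(net)), 25L)
  ff <- extract_free_fluxes(net)
  expect_identical(ff$n_free, 11L)
  expect_identical(dim(build_stoichiometry(net)), c(25L, 60L))

  net2 <- load_network(cho_network_path("noncompartmented"))
  expect_length(net2$reactions, 42L)
  expect_identical(dim(build_stoichiometry(net2)), c(16L, 42L))
  expect_identical(extract_free_fluxes(net2)$n_free, 5L)
})

test_that("free-flux count matches the exact rational-rank oracle", {
  for (which in c("compartmented", "noncompartmented")) {
    net <- load_network(cho_network_path(which))
    sys <- rational_system(net)
    rk <- rational_rank(sys$num, sys$den)
    ff <- extract_free_fluxes(net)
    expect_identical(ff$rank, rk)
    expect_identical(ff$n_free, length(net$reactions) - rk)
  }
})

test_that("carbon-count mismatches and malformed maps are rejected", {
  bad <- write_net(c(
    "name bad", "met A 2 cytosolic balanced", "met B 3 cytosolic balanced",
    "rxn r1: A (ab) -> B (ab)"))
  expect_error(load_network(bad), "carbon")

  lost <- write_net(c(
    "name lost", "met A 3 cytosolic balanced", "met B 2 cytosolic balanced",
    "rxn r1: A (abc) -> B (ab)"))
  expect_error(load_network(lost), "not transferred")

  dup <- write_net(c(
    "name dup", "met A 2 cytosolic balanced", "met B 2 cytosolic balanced",
    "met C 2 cytosolic balanced",
    "rxn r1: A (ab) -> B (ab) + C (ab)"))
  expect_error(load_network(dup), "twice")
})

test_that("stoichiometry columns follow net coefficients over balanced rows", {
  chain <- load_network(write_net(c(
    "name chain",
    "met A_ex 1 extracellular dynamic", "met B 1 cytosolic balanced",
    "met C 1 cytosolic sink",
    "rxn r1: A_ex (a) -> B (a)", "rxn r2: B (a) -> C (a)",
    "measure r1 = 10")))
  G <- build_stoichiometry(chain)
  expect_equal(unname(G), matrix(c(1, -1), 1))
  ff <- extract_free_fluxes(chain)
  expect_identical(ff$n_free, 0L)
  v <- ff$solver(numeric(0))
  expect_equal(unname(v), c(10, 10))

  two <- load_network(write_net(c(
    "name two", "met A 1 cytosolic balanced", "met B 2 cytosolic sink",
    "met S_ex 1 extracellular dynamic",
    "rxn upt: S_ex (a) -> A (a)",
    "rxn r: 2 A -> B")))
  G2 <- build_stoichiometry(two)
  expect_equal(G2["A", "r"], -2)
})

test_that("diamond network has one free flux (the branch split)", {
  diamond <- load_network(write_net(c(
    "name diamond",
    "met S_ex 1 extracellular dynamic", "met A 1 cytosolic balanced",
    "met B 1 cytosolic balanced", "met C 1 cytosolic balanced",
    "met D 1 cytosolic sink",
    "rxn upt: S_ex (a) -> A (a)",
    "rxn ab: A (a) -> B (a)", "rxn ac: A (a) -> C (a)",
    "rxn bd: B (a) -> D (a)", "rxn cd: C (a) -> D (a)",
    "measure upt = 10", "prefer_free ab")))
  ff <- extract_free_fluxes(diamond)
  expect_identical(ff$n_free, 1L)
  expect_identical(ff$free, "ab")
  v <- ff$solver(c(ab = 4))
  expect_equal(unname(v[c("ac", "bd", "cd")]), c(6, 4, 6))
})

test_that("solver satisfies G v = 0 for random free-flux assignments", {
  net <- load_network(cho_network_path("compartmented"))
  ff <- extract_free_fluxes(net)
  set.seed(42)
  for (i in 1:20) {
    x <- setNames(runif(ff$n_free, -50, 400), ff$free)
    v <- ff$solver(x)
    expect_lt(max(abs(ff$G %*% v)), 1e-8 * max(abs(v), 1))
    expect_equal(unname(v[ff$free]), unname(x))
    # measured rates reproduced
    expect_equal(unname((ff$measured$E %*% v)[, 1]), unname(ff$measured$phi))
  }
})

test_that("inconsistent measured rates raise an infeasibility error", {
  # chain with both ends measured inconsistently
  bad <- load_network(write_net(c(
    "name badmeas",
    "met A_ex 1 extracellular dynamic", "met B 1 cytosolic balanced",
    "met C_ex 1 extracellular dynamic",
    "rxn r1: A_ex (a) -> B (a)", "rxn r2: B (a) -> C_ex (a)",
    "measure r1 = 10", "measure r2 = 12")))
  ff <- extract_free_fluxes(bad)
  expect_identical(ff$n_free, 0L)
  expect_error(ff$solver(numeric(0)), "inconsistent")
})

test_that("reference flux distribution is feasible and bound-checked", {
  net <- load_network(cho_network_path("compartmented"))
  ff <- extract_free_fluxes(net)
  v <- ff$solver(cho_truth_free())
  expect_true(isTRUE(check_flux_vector(net, v)))
  expect_equal(unname(v["glc_upt"]), 371.0)
  expect_equal(unname(v["lac_ex"]), 289.4)
  # bound violation is reported, not clipped
  v2 <- v; v2["pk"] <- -5
  expect_warning(viol <- check_flux_vector(net, v2), "violated")
  expect_true("pk" %in% viol$reaction)
})

test_that("network report lists rank and free fluxes", {
  net <- load_network(cho_network_path("compartmented"))
  path <- tempfile(fileext = ".json")
  rep <- network_report(net, path)
  expect_identical(rep$n_free, 11L)
  expect_true(file.exists(path))
  back <- jsonlite::read_json(path)
  expect_identical(back$rank, 49L)
})
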