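# Objective, chi-squared thresholds, global optimization on the toy
# network, profile confidence intervals, sensitivities.

test_that("SSQD is a weighted sum of squares with the expected properties", {
  expect_equal(ssqd(c(1, 2), c(1, 2), c(1, 1)), 0)
  # one residual of 0.01 at the floored sd 0.005 contributes 4
  expect_equal(ssqd(0.51, 0.50, build_covariance(0.001)), 4)
  a <- ssqd(c(0.1, 0.2), c(0.11, 0.18), c(1, 2) * 1e-4)
  b <- ssqd(0.1, 0.11, 1e-4) + ssqd(0.2, 0.18, 2e-4)
  expect_equal(a, b)
  # invariant under reordering of residual blocks
  o <- c(2, 1)
  expect_equal(ssqd(c(0.1, 0.2)[o], c(0.11, 0.18)[o], (c(1, 2) * 1e-4)[o]), a)
  expect_error(ssqd(1:3, 1:2, rep(1, 3)), "differ")
})

test_that("chi-squared thresholds reproduce published table values", {
  expect_equal(chi2_threshold(252, 24), 264.2, tolerance = 0.05 / 264.2)
  expect_equal(chi2_threshold(252, 38), 249.13, tolerance = 0.05 / 249.13)
  expect_equal(chi2_threshold(2, 1), 3.841, tolerance = 1e-3)
  # standard chi-squared quantiles at assorted dof
  ref <- c(`1` = 3.8415, `10` = 18.3070, `100` = 124.3421)
  for (d in names(ref))
    expect_equal(qchisq(0.95, as.integer(d)), ref[[d]], tolerance = 1e-4)
  expect_equal(chi2_threshold(215, 1), qchisq(0.95, 214))
  expect_equal(chi2_threshold(229, 1), qchisq(0.95, 228))
  expect_error(chi2_threshold(10, 10), "N > p")
})

test_that("fit parameter table counts every fitted scalar", {
  net <- load_network(cho_network_path("compartmented"))
  ptab <- fit_parameters(net)
  # 11 free fluxes + 24 constant revs + rev0 + alpha + beta + CO2 pool
  expect_identical(nrow(ptab), 11L + 24L + 3L + 1L)
  expect_identical(sum(ptab$kind == "flux"), 11L)
  net2 <- load_network(cho_network_path("noncompartmented"))
  ptab2 <- fit_parameters(net2)
  # 5 free fluxes + 15 constant revs + rev0 + alpha + beta + CO2 pool = 24
  expect_identical(nrow(ptab2), 24L)
})

test_that("noiseless two-parameter recovery is exact on the toy network", {
  scn <- toy_scenario(dil = 30, rev = 1.0, mid_sd = 0)
  dat <- toy_data(scn)
  fit <- global_fit(scn$network, dat, params = c("dil", "REV_P.rev"),
                    config = list(pop_factor = 10, generations = 10, seed = 1),
                    experiment = scn$experiment)
  expect_lte(fit$ssqd, 1e-3)
  expect_lt(abs(fit$par[["dil"]] - 30) / 30, 0.01)
  expect_lt(abs(fit$par[["REV_P.rev"]] - 1.0), 0.01)
  expect_true(fit$accepted)
})

test_that("identical seeds give identical fits", {
  scn <- toy_scenario(mid_sd = 0.005)
  dat <- toy_data(scn, seed = 3)
  cfg <- list(pop_factor = 6, generations = 4, seed = 11, refine = FALSE)
  f1 <- global_fit(scn$network, dat, params = c("dil", "REV_P.rev"),
                   config = cfg, experiment = scn$experiment)
  f2 <- global_fit(scn$network, dat, params = c("dil", "REV_P.rev"),
                   config = cfg, experiment = scn$experiment)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$ssqd, f2$ssqd)
  expect_identical(f1$trace, f2$trace)
})

test_that("profile intervals match the closed form on a quadratic surface", {
  # SSQD(theta) = a (theta - theta*)^2 has 95% half-width sqrt(3.841/a)
  a <- 2.5
  obj <- list(fn = function(th) a * (th[1] - 4)^2,
              lb = c(q = -50), ub = c(q = 50), params = "q")
  fit <- structure(list(par = c(q = 4), ssqd = 0, objective = obj),
                   class = "instcho_fit")
  ci <- confidence_intervals(fit, n_steps = 60L, reopt = FALSE)
  hw <- sqrt(qchisq(0.95, 1) / a)
  expect_equal(ci$hi - ci$estimate, hw, tolerance = 0.1)
  expect_equal(ci$estimate - ci$lo, hw, tolerance = 0.1)
  expect_false(ci$nd_lo || ci$nd_hi)
})

test_that("parameters pinned at a box bound are flagged not determined", {
  obj <- list(fn = function(th) 0 * th[1],   # flat profile
              lb = c(q = 0), ub = c(q = 10), params = "q")
  fit <- structure(list(par = c(q = 0), ssqd = 0, objective = obj),
                   class = "instcho_fit")
  ci <- confidence_intervals(fit, n_steps = 5L, reopt = FALSE)
  expect_true(ci$nd_lo)   # estimate sits on the lower bound
  expect_true(ci$nd_hi)   # flat profile never crosses the threshold
  expect_equal(ci$hi, 10)
})

test_that("objective sensitivity vanishes for irrelevant parameters", {
  scn <- toy_scenario(mid_sd = 0)
  dat <- toy_data(scn)
  obj <- make_objective(scn$network, dat, params = c("dil", "REV_P.rev"),
                        experiment = scn$experiment)
  fit <- structure(list(par = c(dil = 30, REV_P.rev = 1.0),
                        ssqd = obj$fn(c(30, 1.0)) + 1e-9,
                        objective = obj), class = "instcho_fit")
  s <- sensitivity_of_objective(fit, n_perturb = 20L, seed = 2)
  # at a strict minimum both sensitivities are non-negative
  expect_true(all(s >= 0))
})

test_that("flux sensitivity to a measured rate is 1 for pass-through fluxes", {
  # chain: everything algebraically equals the measured uptake
  net <- load_network(write_net(c(
    "name chain2",
    "met S_ex 2 extracellular dynamic", "met A 2 cytosolic balanced",
    "met P_ex 2 extracellular dynamic",
    "rev REV_O constant rev=0.5",
    "rxn upt: S_ex (ab) -> A (ab)",
    "rxn out: A (ab) -> P_ex (ab), rev_model=REV_O",
    "measure upt = 100")))
  exp_des <- toy_experiment()
  ff <- extract_free_fluxes(net)
  v <- ff$solver(setNames(numeric(0), character(0)))
  set.seed(1)
  sim <- simulate_labeling(net, v, experiment = exp_des,
                           fragments = toy_fragments())
  rows <- do.call(rbind, lapply(seq_along(sim$times), function(ti)
    data.frame(fragment = "P", time_h = sim$times[ti],
               m0 = sim$mids$P[ti, 1], m1 = sim$mids$P[ti, 2],
               m2 = sim$mids$P[ti, 3], sd0 = 0.005, sd1 = 0.005, sd2 = 0.005)))
  dat <- mid_data(rows, toy_fragments())
  fit <- global_fit(net, dat, params = "REV_O.rev",
                    config = list(pop_factor = 4, generations = 2, seed = 1),
                    experiment = exp_des)
  sens <- sensitivity_to_measured(
    fit, data.frame(rate = "upt", lo = 95, hi = 105), net, maxit = 10L)
  expect_equal(unname(sens["upt", "upt"]), 1, tolerance = 1e-6)
  expect_equal(unname(sens["out", "upt"]), 1, tolerance = 0.2)
})
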