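# Metabolite balancing: growth, cell-specific rates, glutamine degradation,
# carbon accounting, cell geometry.

geom <- cell_geometry(10.6)
Xc0_ref <- cell_volume_concentration(4e5, geom)

make_culture <- function(t = seq(0, 72, by = 8), mu = 0.0401, X0 = 4e5,
                         rates = c(), C0 = c(), kd = c(), noise = 0,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- X0 * exp(mu * t)
  df <- data.frame(time_h = t,
                   cell_density = X * (1 + rnorm(length(t), 0, noise)))
  Xc0 <- cell_volume_concentration(X0, geom)
  for (m in names(rates)) {
    k <- if (m %in% names(kd)) kd[[m]] else 0
    cc <- instcho:::conc_profile(t, C0[[m]], rates[[m]], mu, Xc0, k)
    df[[m]] <- cc * (1 + rnorm(length(t), 0, noise))
  }
  df
}

test_that("growth fit recovers the generating rate exactly without noise", {
  ts <- make_culture()
  g <- fit_growth(ts)
  expect_equal(g$mu, 0.0401, tolerance = 1e-10)
  expect_equal(g$X0, 4e5, tolerance = 1e-8)

  flat <- data.frame(time_h = 0:5, cell_density = rep(1e6, 6))
  expect_equal(fit_growth(flat)$mu, 0, tolerance = 1e-12)

  expect_error(fit_growth(data.frame(time_h = 0:3, cell_density = c(1, -1, 1, 1))),
               "non-positive")
})

test_that("growth fit under 2% noise lands within 5% of truth", {
  ts <- make_culture(t = seq(0, 72, length.out = 10), noise = 0.02, seed = 7)
  g <- fit_growth(ts)
  expect_lt(abs(g$mu - 0.0401) / 0.0401, 0.05)
})

test_that("rate fit is exact on noiseless closed-form data", {
  ts <- make_culture(rates = c(GLC = -371, LAC = 289.4),
                     C0 = c(GLC = 42, LAC = 0.2))
  g <- fit_growth(ts)
  r <- fit_rate(ts, g, "GLC")
  expect_equal(r$v, -371, tolerance = 1e-6)
  expect_true(r$ci95[1] <= r$v && r$v <= r$ci95[2])
  expect_equal(fit_rate(ts, g, "LAC")$v, 289.4, tolerance = 1e-6)
})

test_that("glutamine degradation is separated from uptake", {
  ts <- make_culture(rates = c(GLN = -66.4), C0 = c(GLN = 8.4),
                     kd = c(GLN = 0.0033))
  g <- fit_growth(ts)
  r <- fit_rate(ts, g, "GLN", kd = 0.0033)
  expect_equal(r$v, -66.4, tolerance = 1e-6)
  # ignoring degradation absorbs it into apparent uptake: |v| grows
  r0 <- fit_rate(ts, g, "GLN", kd = 0)
  expect_gt(abs(r0$v), abs(r$v))
})

test_that("including kd never increases the apparent uptake magnitude", {
  set.seed(11)
  for (i in 1:5) {
    ts <- make_culture(rates = c(GLN = -runif(1, 40, 90)),
                       C0 = c(GLN = 9), kd = c(GLN = 0.0033),
                       noise = 0.01, seed = i)
    g <- fit_growth(ts)
    v_kd <- fit_rate(ts, g, "GLN", kd = 0.0033)$v
    v_0 <- fit_rate(ts, g, "GLN", kd = 0)$v
    expect_lte(abs(v_kd), abs(v_0) + 1e-9)
  }
})

test_that("carbon accounting reproduces the reference table", {
  rates <- c(Glucose = 371.0, Glutamine = 66.4, AA1 = 92.6, AA2 = 49.6,
             AA3 = 11.6, ASP_ASN = 68.1, Serine = 48.3)
  carb <- c(Glucose = 6, Glutamine = 5, AA1 = 2, AA2 = 4, AA3 = 5,
            ASP_ASN = 4, Serine = 3)
  tab <- carbon_accounting(rates, carb, total = 3428.53)
  expect_equal(tab$cmmol[tab$source == "Glucose"], 2226.2, tolerance = 1e-3)
  expect_equal(tab$cmmol[tab$source == "AA1"], 185.2)
  expect_equal(tab$percent[tab$source == "Glucose"], 64.9, tolerance = 2e-3)

  single <- carbon_accounting(c(x = 10), c(x = 3))
  expect_equal(single$percent, 100)
  # percentages sum to 100 when the total is the column sum
  tab2 <- carbon_accounting(rates, carb)
  expect_equal(sum(tab2$percent), 100)
})

test_that("cell geometry converts diameter to volumetric concentration", {
  expect_equal(geom$single_cell_volume_L, pi / 6 * (10.6e-6)^3 * 1e3)
  expect_equal(geom$single_cell_volume_L, 6.236e-13, tolerance = 1e-3)
  expect_equal(cell_volume_concentration(0, geom), 0)
  expect_equal(cell_volume_concentration(1e6, geom), 6.236e-4, tolerance = 1e-3)
})

test_that("fit_all_rates mirrors the per-metabolite fits", {
  ts <- make_culture(rates = c(GLC_ex = -371, GLN_ex = -66.4),
                     C0 = c(GLC_ex = 42, GLN_ex = 8.4),
                     kd = c(GLN_ex = 0.0033))
  tab <- fit_all_rates(ts, kd = c(GLN_ex = 0.0033))
  expect_equal(tab$v[tab$metabolite == "GLC_ex"], -371, tolerance = 1e-6)
  expect_equal(tab$v[tab$metabolite == "GLN_ex"], -66.4, tolerance = 1e-6)
  expect_true(all(tab$ci_low <= tab$v & tab$v <= tab$ci_high))
})
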