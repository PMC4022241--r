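# Metabolite balancing: specific growth rate and constant cell-specific
# extracellular rates from batch time series, with first-order abiotic
# glutamine degradation; Table-1-style carbon accounting; cell-volume
# conversion from diameter.

#' Cell geometry and volumetric concentration
#'
#' Cells are treated as spheres; the default diameter is the 10.6 um
#' determined for CHO-K1.
#'
#' @param diameter_um cell diameter in micrometers
#' @return list with diameter_um and single_cell_volume_L
#' @export
cell_geometry <- function(diameter_um = 10.6) {
  list(diameter_um = diameter_um,
       single_cell_volume_L = pi / 6 * (diameter_um * 1e-6)^3 * 1e3)
}
# note: (d m)^3 gives m^3; x1e3 converts to litres

#' Cell volumetric concentration Xconc (L cell / L media)
#'
#' Converts a cell density to the volume fraction occupied by cells, the
#' quantity that links cell-specific rates (mmol/(L cell x h)) to medium
#' concentration changes (mM/h).
#'
#' @param density_cells_per_ml cell density, cells/mL
#' @param geometry see [cell_geometry()]
#' @export
cell_volume_concentration <- function(density_cells_per_ml,
                                      geometry = cell_geometry()) {
  stopifnot(all(density_cells_per_ml >= 0))
  density_cells_per_ml * 1e3 * geometry$single_cell_volume_L
}

#' Fit the exponential growth model dX/dt = mu X
#'
#' Log-linear least squares on the cell density. Returns the specific
#' growth rate, the fitted initial density and 95% confidence intervals.
#'
#' @param ts data.frame with columns time_h and cell_density (cells/mL)
#' @return list of class instcho_growth: mu (1/h), X0, ci95_mu, se_mu
#' @export
fit_growth <- function(ts) {
  stopifnot(nrow(ts) >= 3)
  if (any(ts$cell_density <= 0)) stop("non-positive cell densities")
  fit <- lm(log(cell_density) ~ time_h, data = ts)
  mu <- unname(coef(fit)[2])
  # vcov warns on numerically perfect fits; the zero-width CI is correct
  se <- sqrt(diag(suppressWarnings(vcov(fit))))[2]
  V <- suppressWarnings(vcov(fit))
  structure(list(mu = mu, X0 = exp(unname(coef(fit)[1])),
                 se_mu = unname(se),
                 se_lnX0 = sqrt(V[1, 1]), cov_mu_lnX0 = V[1, 2],
                 ci95_mu = mu + c(-1, 1) * qnorm(0.975) * unname(se)),
            class = "instcho_growth")
}

#' @export
print.instcho_growth <- function(x, ...) {
  cat(sprintf("growth fit: mu = %.4f 1/h  (95%% CI %.4f..%.4f), X0 = %.3g cells/mL\n",
              x$mu, x$ci95_mu[1], x$ci95_mu[2], x$X0))
  invisible(x)
}

# Closed-form concentration profile for a constant cell-specific rate v
# (mmol/(L cell x h)) under exponential growth, with optional first-order
# degradation kd (1/h):
#   kd = 0:  C(t) = C0 + v Xc0/mu (e^{mu t} - 1)
#   kd > 0:  C(t) = e^{-kd t} [C0 + v Xc0 (e^{(mu+kd) t} - 1)/(mu + kd)]
#' @keywords internal
conc_profile <- function(t, C0, v, mu, Xc0, kd = 0) {
  if (kd == 0) C0 + v * Xc0 / mu * (exp(mu * t) - 1)
  else exp(-kd * t) * (C0 + v * Xc0 * (expm1((mu + kd) * t)) / (mu + kd))
}

#' Fit a constant cell-specific extracellular rate
#'
#' Least-squares fit of the closed-form solution of
#' dC/dt = v Xconc(t) - kd C(t) to a concentration time series. The sign
#' convention is production > 0, uptake < 0; `kd` models abiotic
#' first-order degradation (glutamine: kd = 0.0033 1/h).
#'
#' @param ts data.frame with columns time_h and the metabolite column
#' @param growth an `instcho_growth` fit
#' @param metabolite name of the concentration column (mM)
#' @param kd first-order degradation constant, 1/h
#' @param geometry cell geometry for the density-to-Xconc conversion
#' @return list of class instcho_rate: v, C0, ci95, se, kd
#' @export
fit_rate <- function(ts, growth, metabolite, kd = 0,
                     geometry = cell_geometry()) {
  stopifnot(kd >= 0, metabolite %in% names(ts))
  t <- ts$time_h
  C <- ts[[metabolite]]
  Xc0 <- cell_volume_concentration(growth$X0, geometry)
  if (kd > 0 && stats::sd(C) == 0)
    warning("constant concentration with kd > 0: v is confounded with C0")
  # model is linear in (C0, v) given (mu, X0): solve by least squares
  solve_v <- function(mu, Xc0) {
    g <- if (kd == 0) (exp(mu * t) - 1) / mu
         else exp(-kd * t) * expm1((mu + kd) * t) / (mu + kd)
    X <- cbind(C0 = if (kd == 0) rep(1, length(t)) else exp(-kd * t),
               v = Xc0 * g)
    fit <- lm.fit(X, C)
    list(cf = fit$coefficients, X = X, res = fit$residuals)
  }
  fit <- solve_v(growth$mu, Xc0)
  cf <- fit$cf
  dof <- length(t) - 2L
  s2 <- sum(fit$res^2) / max(dof, 1L)
  XtXi <- chol2inv(chol(crossprod(fit$X)))
  se_conc <- sqrt(s2 * diag(XtXi))[2]
  # propagate growth-model uncertainty (mu, ln X0) by the delta method:
  # v scales as 1/X0, and the regressor shape depends on mu
  dv_dlnX0 <- -cf[["v"]]
  h <- max(1e-6, 1e-3 * abs(growth$mu))
  dv_dmu <- (solve_v(growth$mu + h, Xc0)$cf[["v"]] -
             solve_v(growth$mu - h, Xc0)$cf[["v"]]) / (2 * h)
  var_growth <- if (!is.null(growth$se_lnX0))
    dv_dmu^2 * growth$se_mu^2 + dv_dlnX0^2 * growth$se_lnX0^2 +
      2 * dv_dmu * dv_dlnX0 * growth$cov_mu_lnX0 else 0
  se <- sqrt(se_conc^2 + var_growth)
  structure(list(metabolite = metabolite, v = unname(cf["v"]),
                 C0 = unname(cf["C0"]), kd = kd,
                 se = unname(se),
                 ci95 = unname(cf["v"]) + c(-1, 1) * qnorm(0.975) * unname(se),
                 residuals = unname(fit$res)),
            class = "instcho_rate")
}

#' @export
print.instcho_rate <- function(x, ...) {
  cat(sprintf("%s: v = %.3f mmol/(L cell x h) (95%% CI %.3f..%.3f)%s\n",
              x$metabolite, x$v, x$ci95[1], x$ci95[2],
              if (x$kd > 0) sprintf(", kd = %.4f 1/h", x$kd) else ""))
  invisible(x)
}

#' Fit all extracellular rates of a culture table
#'
#' @param ts culture data.frame (time_h, cell_density, one column per
#'   metabolite in mM)
#' @param growth optional pre-fitted growth model
#' @param kd named vector of degradation constants (default: GLN 0.0033)
#' @return data.frame with metabolite, v, ci_low, ci_high, kd
#' @export
fit_all_rates <- function(ts, growth = NULL, kd = c(GLN = 0.0033)) {
  if (is.null(growth)) growth <- fit_growth(ts)
  mets <- setdiff(names(ts), c("time_h", "cell_density"))
  mets <- mets[!grepl("_sd$", mets)]
  rows <- lapply(mets, function(m) {
    k <- if (m %in% names(kd)) kd[[m]] else 0
    r <- fit_rate(ts, growth, m, kd = k)
    data.frame(metabolite = m, v = r$v, ci_low = r$ci95[1],
               ci_high = r$ci95[2], kd = k)
  })
  out <- do.call(rbind, rows)
  attr(out, "growth") <- growth
  out
}

#' Carbon-source accounting (Table-1 style)
#'
#' Converts uptake rates of the carbon sources feeding central metabolism
#' into Cmmol fluxes (rate x carbons transferred to the target metabolite)
#' and percentages of the total carbon influx.
#'
#' @param uptake_rates named non-negative vector, mmol/(L cell x h)
#' @param carbons_to_target named integer vector, carbons reaching the
#'   target intracellular metabolite (e.g. 2 for the acetyl-CoA-forming
#'   amino acid lump)
#' @param total optional externally printed total used for the percentage
#'   column (defaults to the column sum)
#' @return data.frame with source, rate, cmmol, percent
#' @export
carbon_accounting <- function(uptake_rates, carbons_to_target, total = NULL) {
  stopifnot(all(uptake_rates >= 0),
            all(names(uptake_rates) %in% names(carbons_to_target)) ||
              length(uptake_rates) == length(carbons_to_target))
  carbons <- if (!is.null(names(uptake_rates)) && all(names(uptake_rates) %in% names(carbons_to_target)))
    carbons_to_target[names(uptake_rates)] else carbons_to_target
  cmmol <- unname(uptake_rates * carbons)
  tot <- if (is.null(total)) sum(cmmol) else total
  data.frame(source = names(uptake_rates), rate = unname(uptake_rates),
             carbons = unname(carbons), cmmol = cmmol,
             percent = 100 * cmmol / tot, row.names = NULL)
}
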