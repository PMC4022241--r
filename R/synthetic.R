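# Synthetic batch-culture experiments generated from a known ground truth:
# culture profile (cell density + concentrations), corrected and raw MID
# time courses with noise, and a truth record for recovery tests.

#' Ground-truth free fluxes of the compartmented CHO-K1 fixture
#'
#' Synthetic reference values, chosen so that the implied full flux vector
#' reproduces the printed headline rates (glucose uptake 371, lactate 289.4,
#' oxPPP at 80% of glucose input, PEP-to-lactate channeling 122.7, PEP
#' carboxykinase at 10% of the PEP influx) in mmol/(L cell x h).
#'
#' @export
cho_truth_free <- function() {
  c(ppp = 296.8, chan = 122.7, ala_mt = 2, pc = 60, me_c = 0.5,
    idh_c = 10, pepck = 67.1, glu_mt = 50, gs = 20, ast_m = 13,
    ser_syn = 24)
}

#' Default synthetic CHO-K1 batch scenario
#'
#' Bundles the compartmented network fixture, its ground-truth parameter
#' set (free fluxes above, reversibility values from the network config),
#' CHO-like batch conditions (mu = 0.0401 1/h, X0 = 4e5 cells/mL, glutamine
#' degradation kd = 0.0033 1/h, sampling at 1, 18, 24, 42, 48, 66, 72 h)
#' and the noise model (Gaussian MID noise sd 0.005 with renormalization,
#' 2% concentration/density noise).
#'
#' @param network an `instcho_network`; default: the compartmented fixture
#' @param free ground-truth free-flux values
#' @param experiment batch-experiment description
#' @param mid_sd Gaussian MID noise standard deviation
#' @param conc_cv relative concentration / cell-density noise
#' @param seed default RNG seed
#' @export
cho_default_scenario <- function(network = NULL, free = cho_truth_free(),
                                 experiment = default_experiment(),
                                 mid_sd = 0.005, conc_cv = 0.02, seed = 1L) {
  if (is.null(network)) network <- load_network(cho_network_path("compartmented"))
  ff <- extract_free_fluxes(network)
  if (!setequal(names(free), ff$free))
    stop("ground-truth free fluxes do not match the network's free set: ",
         paste(ff$free, collapse = ", "))
  v <- ff$solver(free[ff$free])
  viol <- check_flux_vector(network, v)
  if (!isTRUE(viol)) stop("infeasible ground truth (flux bounds violated)")
  structure(list(network = network, free = free[ff$free], v = v,
                 experiment = experiment, mid_sd = mid_sd,
                 conc_cv = conc_cv, seed = seed,
                 params = NULL, fixed = NULL),
            class = "instcho_scenario")
}

#' @export
print.instcho_scenario <- function(x, ...) {
  cat("synthetic scenario on '", x$network$name, "', mid sd ",
      x$mid_sd, ", conc cv ", x$conc_cv,
      if (!is.null(x$params)) paste0(", reduced to ",
                                     length(x$params), " free parameters"),
      "\n", sep = "")
  invisible(x)
}

#' Generate a synthetic labeling experiment
#'
#' Simulates the scenario's ground truth, adds Gaussian noise (MID fractions
#' are perturbed, clipped at zero and renormalized; the reported standard
#' deviation is the nominal noise magnitude, i.e. measurement error is
#' treated as known), forward-convolves natural abundance to produce raw
#' spectra for testing the correction, and samples a noisy culture profile.
#'
#' @param scenario an `instcho_scenario`
#' @param seed RNG seed (defaults to the scenario's)
#' @param out_dir optional directory: writes culture.csv, mids_corrected.csv,
#'   mids_raw.csv and truth.json
#' @param culture_times sampling grid of the culture profile
#' @return list with culture, mids_corrected, mids_raw (data.frames),
#'   truth (list) and sim (the noiseless `instcho_sim`)
#' @export
generate_experiment <- function(scenario, seed = NULL, out_dir = NULL,
                                culture_times = seq(0, 72, by = 8)) {
  stopifnot(inherits(scenario, "instcho_scenario"))
  set.seed(seed %||% scenario$seed)
  net <- scenario$network
  exp_des <- scenario$experiment
  frags <- default_fragments()
  sim <- simulate_labeling(net, scenario$v, experiment = exp_des,
                           fragments = frags)

  # corrected MIDs with renormalized additive noise
  rows_c <- rows_r <- list()
  for (k in seq_len(nrow(frags))) {
    fr <- frags$fragment[k]
    m <- sim$mids[[fr]]
    nb <- frags$n_backbone[k]
    for (ti in seq_along(sim$times)) {
      x <- m[ti, ]
      if (scenario$mid_sd > 0) {
        xn <- x + rnorm(length(x), 0, scenario$mid_sd)
        xn[xn < 0] <- 0
        xn <- xn / sum(xn)
      } else xn <- x
      sdv <- rep(scenario$mid_sd, length(x))
      # raw spectra carry two extra masses for the heavy Si/O isotopes of
      # the derivatization group (as a SIM acquisition would)
      nraw <- min(nb + 2L, 6L) + 1L
      raw <- convolve_natural_abundance(xn, frags[k, ], n_raw = nraw)
      row <- data.frame(fragment = fr, time_h = sim$times[ti])
      rowr <- row
      for (j in 0:6) {
        row[[paste0("m", j)]] <- if (j <= nb) xn[j + 1] else NA_real_
        row[[paste0("sd", j)]] <- if (j <= nb) sdv[j + 1] else NA_real_
        rowr[[paste0("m", j)]] <- if (j < nraw) raw[j + 1] else NA_real_
      }
      rows_c[[length(rows_c) + 1L]] <- row
      rows_r[[length(rows_r) + 1L]] <- rowr
    }
  }
  mids_corrected <- do.call(rbind, rows_c)
  mids_raw <- do.call(rbind, rows_r)

  # culture profile
  mu <- exp_des$growth$mu
  Xc0 <- cell_volume_concentration(exp_des$growth$X0, exp_des$geometry)
  dynD <- build_sim_plan(net, exp_des$tracer)$dynD
  vdyn <- as.numeric(dynD %*% scenario$v)
  names(vdyn) <- rownames(dynD)
  culture <- data.frame(time_h = culture_times)
  X <- exp_des$growth$X0 * exp(mu * culture_times)
  culture$cell_density <- X * (1 + rnorm(length(X), 0, scenario$conc_cv))
  for (id in names(exp_des$C0)) {
    kd <- if (id %in% names(exp_des$kd)) exp_des$kd[[id]] else 0
    cc <- dyn_conc(culture_times, exp_des$C0[[id]],
                   if (id %in% names(vdyn)) vdyn[[id]] else 0, mu, Xc0, kd)
    cc <- cc * (1 + rnorm(length(cc), 0, scenario$conc_cv))
    culture[[id]] <- pmax(cc, 0)
  }

  truth <- list(network = net$name, free = as.list(scenario$free),
                v = as.list(scenario$v),
                mu = mu, X0 = exp_des$growth$X0,
                kd = as.list(exp_des$kd),
                mid_sd = scenario$mid_sd, conc_cv = scenario$conc_cv,
                params = scenario$params, fixed = scenario$fixed)

  out <- list(culture = culture, mids_corrected = mids_corrected,
              mids_raw = mids_raw, truth = truth, sim = sim)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(culture, file.path(out_dir, "culture.csv"), row.names = FALSE)
    write_mid_csv(mids_corrected, file.path(out_dir, "mids_corrected.csv"))
    write_mid_csv(mids_raw, file.path(out_dir, "mids_raw.csv"))
    jsonlite::write_json(truth, file.path(out_dir, "truth_synthetic.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

#' Reduce a scenario to a small fitted-parameter set
#'
#' Freezes all but `n_free_params` parameters at their ground-truth values
#' so that a desk-scale optimization (minutes, not hours) still exercises
#' the complete fitting stack. Parameters are released in a fixed order:
#' the pathway-split free fluxes first.
#'
#' @param scenario an `instcho_scenario`
#' @param n_free_params number of parameters to fit (0 allowed: pure
#'   simulation check)
#' @param order preferred release order (parameter names)
#' @return the scenario with `params` (fitted names) and `fixed` (truth
#'   values of the frozen free fluxes) set
#' @export
make_reduced_scenario <- function(scenario, n_free_params,
                                  order = NULL) {
  stopifnot(inherits(scenario, "instcho_scenario"))
  ptab <- fit_parameters(scenario$network)
  avail <- ptab$name
  order <- order %||% c(intersect(c("ppp", "chan", "pepck", "pc", "glu_mt",
                                    "gs", "me_c", "idh_c", "ala_mt", "ast_m",
                                    "ser_syn"), avail),
                        setdiff(avail, c(names(scenario$free), "co2_pool")))
  order <- unique(order)
  if (n_free_params > length(order))
    stop("requested ", n_free_params, " free parameters but only ",
         length(order), " are available")
  scenario$params <- head(order, n_free_params)
  fixed <- as.list(scenario$free[setdiff(names(scenario$free), scenario$params)])
  scenario$fixed <- fixed
  scenario
}
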