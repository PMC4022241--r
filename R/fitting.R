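# Parameter estimation: weighted least-squares objective over measured MID
# time courses, chi-squared model acceptance, three-stage global
# optimization (feasible-population sampling -> genetic algorithm -> local
# refinement), profile-likelihood confidence intervals and the two
# sensitivity analyses.

#' Covariance-weighted sum of squared MID differences
#'
#' SSQD = (sim - exp)' Sigma^-1 (sim - exp) with diagonal Sigma.
#'
#' @param sim_mids,exp_mids numeric vectors (or matrices flattened in the
#'   same order)
#' @param covariance diagonal covariance matrix from [build_covariance()],
#'   or a vector of variances
#' @export
ssqd <- function(sim_mids, exp_mids, covariance) {
  s <- as.numeric(sim_mids); e <- as.numeric(exp_mids)
  if (length(s) != length(e)) stop("sim and exp MID dimensions differ")
  v <- if (is.matrix(covariance)) diag(covariance) else as.numeric(covariance)
  if (length(v) != length(s)) stop("covariance dimension mismatch")
  sum((s - e)^2 / v)
}

#' Chi-squared acceptance threshold
#'
#' @param n_data number of mass-isotopomer data points N
#' @param n_params number of free parameters p
#' @param prob acceptance probability (default 0.95)
#' @return upper quantile of the chi-squared distribution with N - p dof
#' @export
chi2_threshold <- function(n_data, n_params, prob = 0.95) {
  if (n_data <= n_params) stop("need N > p for the chi-squared test")
  qchisq(prob, df = n_data - n_params)
}

#' Fittable parameters of a network
#'
#' One row per fitted scalar: the free net fluxes, every reversibility
#' scalar (constant `rev`, hyperbolic `rev0`, exponential `alpha`/`beta`;
#' the hyperbolic epsilon is a fixed regularizer) and the dissolved-CO2
#' pool size.
#'
#' @param network an `instcho_network`
#' @param vmax free-flux bound magnitude
#' @param rev_max upper bound for constant reversibilities
#' @return data.frame name, kind, lb, ub, default
#' @export
fit_parameters <- function(network, vmax = 1500, rev_max = 50) {
  ff <- extract_free_fluxes(network)
  rows <- list()
  for (id in ff$free) {
    r <- network$reactions[[id]]
    lb <- if (!is.na(r$lb)) r$lb else if (r$reversible) -vmax else 0
    ub <- if (!is.na(r$ub)) r$ub else vmax
    rows[[length(rows) + 1L]] <- data.frame(
      name = id, kind = "flux", lb = lb, ub = ub, default = NA_real_)
  }
  seen <- character()
  for (r in network$reactions) {
    if (!r$reversible || is.na(r$rev_model) || r$rev_model %in% seen) next
    seen <- c(seen, r$rev_model)
    m <- network$rev_models[[r$rev_model]]
    if (m$kind == "constant") {
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste0(m$id, ".rev"), kind = "rev",
        lb = 0, ub = rev_max, default = m$rev)
    } else if (m$kind == "hyperbolic") {
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste0(m$id, ".rev0"), kind = "rev",
        lb = 0, ub = 1e5, default = m$rev0)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste0(m$id, ".alpha"), kind = "rev",
        lb = 0, ub = 10, default = m$alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste0(m$id, ".beta"), kind = "rev",
        lb = 0, ub = 0.15, default = m$beta)
    }
  }
  if (length(Filter(function(m) m$role == "co2", network$metabolites)))
    rows[[length(rows) + 1L]] <- data.frame(
      name = "co2_pool", kind = "pool", lb = 0.05, ub = 50, default = 1)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble MID measurements for fitting
#'
#' Flattens a measurement table (columns fragment, time_h, m0.., sd0..)
#' into the residual ordering used by the objective (fragment table order,
#' times ascending, masses 0..n) and builds the floored covariance.
#'
#' @param df MID measurement data.frame
#' @param fragments fragment table
#' @param sd_floor covariance floor (default 0.005)
#' @return list with times, exp, sd, var (floored variances), N
#' @export
mid_data <- function(df, fragments = default_fragments(), sd_floor = 0.005) {
  lst <- mid_table_to_list(df, fragments)
  times <- sort(unique(df$time_h))
  expv <- sdv <- numeric(0)
  for (k in seq_len(nrow(fragments))) {
    fr <- fragments$fragment[k]
    if (is.null(lst[[fr]])) stop("missing fragment in data: ", fr)
    if (!isTRUE(all.equal(lst[[fr]]$time, times)))
      stop("fragment ", fr, " has a different time grid")
    expv <- c(expv, as.numeric(t(lst[[fr]]$mid)))
    sd <- lst[[fr]]$sd
    if (is.null(sd)) sd <- matrix(sd_floor, nrow(lst[[fr]]$mid), ncol(lst[[fr]]$mid))
    sdv <- c(sdv, as.numeric(t(sd)))
  }
  list(times = times, exp = expv, sd = sdv,
       var = pmax(sdv, sd_floor)^2, N = length(expv),
       fragments = fragments)
}

# Flatten simulated MIDs in the same ordering as mid_data().
sim_mid_vector <- function(sim, fragments) {
  unlist(lapply(fragments$fragment, function(fr) as.numeric(t(sim$mids[[fr]]))),
         use.names = FALSE)
}

#' Build the fitting objective for a network and dataset
#'
#' Returns the SSQD objective over the chosen fitted parameters; all other
#' parameters are held at `fixed` values (free fluxes) or their config
#' defaults (reversibilities, CO2 pool). Parameter sets whose implied full
#' flux vector violates the direction bounds are penalized without
#' simulation.
#'
#' @param network an `instcho_network`
#' @param data result of [mid_data()]
#' @param params character vector of fitted parameter names (subset of
#'   `fit_parameters(network)$name`)
#' @param fixed named list/vector of values for non-fitted free fluxes
#'   (required when not all free fluxes are fitted)
#' @param experiment batch-experiment description
#' @param pool_sizes intracellular pool sizes
#' @param rtol integrator tolerance used during optimization
#' @return list with `fn(theta)`, `lb`, `ub`, `params`, `ptab`,
#'   `simulate(theta)` and `flux(theta)`
#' @export
make_objective <- function(network, data, params = NULL, fixed = NULL,
                           experiment = default_experiment(),
                           pool_sizes = NULL, rtol = 1e-6) {
  ptab <- fit_parameters(network)
  if (is.null(params)) params <- setdiff(ptab$name, "co2_pool")
  bad <- setdiff(params, ptab$name)
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  ff <- extract_free_fluxes(network)
  fixed <- as.list(fixed %||% list())
  miss <- setdiff(ff$free, c(params, names(fixed)))
  if (length(miss))
    stop("free flux(es) neither fitted nor fixed: ", paste(miss, collapse = ", "))
  bounds <- flux_bounds(network)
  lb <- setNames(ptab$lb[match(params, ptab$name)], params)
  ub <- setNames(ptab$ub[match(params, ptab$name)], params)

  unpack <- function(theta) {
    theta <- setNames(as.numeric(theta), params)
    free <- setNames(numeric(length(ff$free)), ff$free)
    for (id in ff$free)
      free[id] <- if (id %in% params) theta[[id]] else as.numeric(fixed[[id]])
    rev <- theta[grepl("\\.", params)]
    co2 <- if ("co2_pool" %in% params) theta[["co2_pool"]]
           else if (!is.null(fixed$co2_pool)) as.numeric(fixed$co2_pool) else 1
    list(free = free, rev = rev, co2 = co2)
  }

  flux <- function(theta) {
    u <- unpack(theta)
    ff$solver(u$free)
  }

  simulate <- function(theta, rtol_use = rtol) {
    u <- unpack(theta)
    v <- ff$solver(u$free)
    ps <- default_pool_sizes(network, overrides = pool_sizes, co2_pool = u$co2)
    simulate_labeling(network, v, experiment = experiment,
                      rev_params = u$rev, pool_sizes = ps,
                      fragments = data$fragments, times = data$times,
                      rtol = rtol_use)
  }

  fn <- function(theta) {
    u <- unpack(theta)
    v <- try(ff$solver(u$free), silent = TRUE)
    if (inherits(v, "try-error")) return(1e10)
    viol <- sum(pmax(bounds$lb - v[bounds$reaction], 0) +
                pmax(v[bounds$reaction] - bounds$ub, 0))
    if (viol > 1e-6) return(1e6 * (1 + viol))
    sim <- suppressWarnings(try(simulate(theta), silent = TRUE))
    if (inherits(sim, "try-error")) return(1e8)
    ssqd(sim_mid_vector(sim, data$fragments), data$exp, data$var)
  }

  list(fn = fn, lb = lb, ub = ub, params = params, ptab = ptab,
       unpack = unpack, simulate = simulate, flux = flux, ff = ff,
       feasible = function(theta) {
         u <- unpack(theta)
         v <- try(ff$solver(u$free), silent = TRUE)
         if (inherits(v, "try-error")) return(Inf)
         sum(pmax(bounds$lb - v[bounds$reaction], 0) +
             pmax(v[bounds$reaction] - bounds$ub, 0))
       })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stage 1: sample a feasible population in the parameter box. Rejection
# sampling with an annealed random-walk repair of the dependent-flux bound
# violations for draws that start infeasible.
sample_feasible <- function(obj, n, max_reject = 50L, anneal_steps = 200L) {
  p <- length(obj$params)
  pop <- matrix(NA_real_, n, p, dimnames = list(NULL, obj$params))
  draw <- function() obj$lb + runif(p) * (obj$ub - obj$lb)
  for (i in seq_len(n)) {
    best <- NULL; best_viol <- Inf
    for (k in seq_len(max_reject)) {
      x <- draw()
      viol <- obj$feasible(x)
      if (viol <= 1e-6) { best <- x; best_viol <- 0; break }
      if (viol < best_viol) { best <- x; best_viol <- viol }
    }
    if (best_viol > 1e-6) {
      # annealed repair: random walk accepting uphill moves with
      # decreasing probability, minimizing the bound violation
      x <- best; vx <- best_viol
      for (s in seq_len(anneal_steps)) {
        Temp <- best_viol * (1 - s / anneal_steps)^2 + 1e-9
        y <- x + rnorm(p) * 0.05 * (obj$ub - obj$lb)
        y <- pmin(pmax(y, obj$lb), obj$ub)
        vy <- obj$feasible(y)
        if (vy < vx || runif(1) < exp(-(vy - vx) / Temp)) { x <- y; vx <- vy }
        if (vx <= 1e-6) break
      }
      best <- x
    }
    pop[i, ] <- best
  }
  pop
}

# Stage 2: real-coded genetic algorithm (tournament selection, blend
# crossover, bounded Gaussian mutation, elitism).
run_ga <- function(obj, pop, generations, trace = TRUE) {
  n <- nrow(pop); p <- ncol(pop)
  fit <- apply(pop, 1, obj$fn)
  hist <- numeric(generations)
  span <- obj$ub - obj$lb
  for (g in seq_len(generations)) {
    newpop <- matrix(NA_real_, n, p, dimnames = dimnames(pop))
    best <- which.min(fit)
    newpop[1, ] <- pop[best, ]   # elitism
    for (i in 2:n) {
      i1 <- sample.int(n, 2); i2 <- sample.int(n, 2)
      pa <- pop[i1[which.min(fit[i1])], ]
      pb <- pop[i2[which.min(fit[i2])], ]
      child <- if (runif(1) < 0.9) {
        a <- runif(p, -0.5, 1.5)   # BLX-style blend
        a * pa + (1 - a) * pb
      } else pa
      mut <- runif(p) < 0.2
      child[mut] <- child[mut] + rnorm(sum(mut)) * 0.1 * span[mut]
      newpop[i, ] <- pmin(pmax(child, obj$lb), obj$ub)
    }
    pop <- newpop
    fit <- apply(pop, 1, obj$fn)
    hist[g] <- min(fit)
  }
  best <- which.min(fit)
  list(par = pop[best, ], value = fit[best], pop = pop, fit = fit,
       trace = hist)
}

# Local refinement: bounded quasi-Newton in two passes with decreasing
# finite-difference steps; the first pass must stay above the ODE
# integrator noise in the objective, the second resolves shallow
# correlated valleys.
refine_local <- function(obj, start, maxit = 100L) {
  best <- list(par = setNames(as.numeric(start), obj$params),
               value = obj$fn(start))
  for (scale in c(3e-4, 2e-5)) {
    ndeps <- pmax(scale * (obj$ub - obj$lb), 1e-7)
    res <- stats::optim(best$par, obj$fn, method = "L-BFGS-B",
                        lower = obj$lb, upper = obj$ub,
                        control = list(maxit = maxit, ndeps = ndeps,
                                       factr = 1e7))
    if (res$value <= best$value)
      best <- list(par = setNames(res$par, obj$params), value = res$value)
  }
  best
}

#' Three-stage global parameter estimation
#'
#' (1) generate a feasible random population of pop_factor x p parameter
#' sets by annealed rejection sampling, (2) evolve it with a
#' generations-long genetic algorithm, (3) refine the best solution with a
#' bounded quasi-Newton local search. The fit is accepted when the
#' minimized SSQD passes the chi-squared test at `prob` with N - p degrees
#' of freedom. Deterministic under a fixed seed.
#'
#' @param network an `instcho_network`
#' @param data [mid_data()] measurements
#' @param params fitted parameter names (default: every free flux and
#'   reversibility scalar)
#' @param fixed values for non-fitted free fluxes / `co2_pool`
#' @param config list: pop_factor (40), generations (50), seed (1),
#'   refine (TRUE), prob (0.95), rtol (1e-6)
#' @param experiment,pool_sizes forwarded to the objective
#' @return object of class `instcho_fit`
#' @export
global_fit <- function(network, data, params = NULL, fixed = NULL,
                       config = list(),
                       experiment = default_experiment(),
                       pool_sizes = NULL) {
  cfg <- modifyList(list(pop_factor = 40, generations = 50, seed = 1,
                         refine = TRUE, refine_maxit = 60, prob = 0.95,
                         rtol = 1e-6), config)
  obj <- make_objective(network, data, params = params, fixed = fixed,
                        experiment = experiment, pool_sizes = pool_sizes,
                        rtol = cfg$rtol)
  p <- length(obj$params)
  set.seed(cfg$seed)
  pop <- sample_feasible(obj, max(cfg$pop_factor * p, 4L))
  ga <- run_ga(obj, pop, cfg$generations)
  best <- list(par = setNames(ga$par, obj$params), value = ga$value)
  if (cfg$refine) {
    ref <- refine_local(obj, best$par, maxit = cfg$refine_maxit)
    if (ref$value <= best$value) best <- ref
  }
  thr <- chi2_threshold(data$N, p, cfg$prob)
  structure(list(
    par = best$par, ssqd = best$value,
    n_data = data$N, n_par = p, dof = data$N - p,
    chi2_threshold = thr, accepted = best$value <= thr,
    trace = ga$trace, config = cfg, params = obj$params,
    fixed = fixed, experiment = experiment,
    objective = obj, data = data, network_name = network$name
  ), class = "instcho_fit")
}

#' @export
print.instcho_fit <- function(x, ...) {
  cat(sprintf("fit of '%s': SSQD = %.2f vs chi2(%.2g, %d) = %.2f -> %s\n",
              x$network_name, x$ssqd, x$config$prob, x$dof,
              x$chi2_threshold, if (x$accepted) "accepted" else "rejected"))
  cat("p =", x$n_par, "fitted parameters; N =", x$n_data, "MID data points\n")
  invisible(x)
}

#' Profile-likelihood confidence intervals
#'
#' For each fitted parameter, walks outward from the optimum re-optimizing
#' the remaining parameters until the profile SSQD exceeds
#' SSQD* + chi2(prob, 1); the crossing is located by interpolation.
#' Endpoints that run into the box bounds are flagged not-determined
#' (`nd`), mirroring the flat profiles of high reversibilities.
#'
#' @param fit an `instcho_fit`
#' @param parameters subset of fitted parameters (default all)
#' @param prob confidence level
#' @param n_steps profile steps per side
#' @param reopt re-optimize the other parameters at each step (profile
#'   likelihood); FALSE gives the cheaper fixed-parameter profile
#' @param maxit local-refinement iterations per step
#' @return data.frame parameter, estimate, lo, hi, nd_lo, nd_hi
#' @export
confidence_intervals <- function(fit, parameters = NULL, prob = 0.95,
                                 n_steps = 6L, reopt = TRUE, maxit = 30L) {
  obj <- fit$objective
  parameters <- parameters %||% obj$params
  target <- fit$ssqd + qchisq(prob, 1)
  out <- list()
  for (pn in parameters) {
    i <- match(pn, obj$params)
    est <- fit$par[[pn]]
    res <- c(lo = NA_real_, hi = NA_real_)
    nd <- c(lo = FALSE, hi = FALSE)
    for (side in c("lo", "hi")) {
      bound <- if (side == "lo") obj$lb[[pn]] else obj$ub[[pn]]
      if (abs(est - bound) < 1e-12) { res[side] <- bound; nd[side] <- TRUE; next }
      steps <- est + (bound - est) * (seq_len(n_steps) / n_steps)^1.5
      prev_x <- est; prev_f <- fit$ssqd
      found <- FALSE
      start <- fit$par
      for (x in steps) {
        thv <- start; thv[i] <- x
        fx <- if (reopt && length(obj$params) > 1L) {
          sub <- profile_reopt(obj, i, x, start, maxit)
          start <- sub$full
          sub$value
        } else obj$fn(thv)
        if (fx >= target) {
          # bisection refinement of the crossing (the profile is convex;
          # chord interpolation would bias the interval inward)
          lo_x <- prev_x; hi_x <- x
          for (b in seq_len(6L)) {
            mid <- (lo_x + hi_x) / 2
            fm <- if (reopt && length(obj$params) > 1L) {
              profile_reopt(obj, i, mid, start, maxit)$value
            } else { thm <- start; thm[i] <- mid; obj$fn(thm) }
            if (fm >= target) hi_x <- mid else lo_x <- mid
          }
          res[side] <- (lo_x + hi_x) / 2
          found <- TRUE
          break
        }
        prev_x <- x; prev_f <- fx
      }
      if (!found) { res[side] <- bound; nd[side] <- TRUE }
    }
    out[[pn]] <- data.frame(parameter = pn, estimate = est,
                            lo = min(res), hi = max(res),
                            nd_lo = nd[["lo"]], nd_hi = nd[["hi"]])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# re-optimize all parameters except index i (held at value x)
profile_reopt <- function(obj, i, x, start, maxit = 30L) {
  keep <- setdiff(seq_along(obj$params), i)
  fn_sub <- function(th) {
    full <- numeric(length(obj$params))
    full[keep] <- th; full[i] <- x
    obj$fn(full)
  }
  ndeps <- pmax(3e-4 * (obj$ub[keep] - obj$lb[keep]), 1e-5)
  res <- stats::optim(start[keep], fn_sub, method = "L-BFGS-B",
                      lower = obj$lb[keep], upper = obj$ub[keep],
                      control = list(maxit = maxit, ndeps = ndeps,
                                     factr = 1e10))
  res$objective <- res$value
  full <- numeric(length(obj$params))
  full[keep] <- res$par; full[i] <- x
  list(value = res$objective, full = setNames(full, obj$params))
}

#' Sensitivity of estimated fluxes to the measured rates
#'
#' Each measured rate is moved to the border of its confidence interval,
#' the model is re-estimated (local refinement from the converged
#' solution), and the normalized response
#' Sens = (dv_e / v_e*) / (dv_m / v_m*) is reported for every net flux.
#'
#' @param fit an `instcho_fit`
#' @param measured_ci data.frame with columns rate, lo, hi (absolute
#'   values of the measured rates at their CI borders)
#' @param network the fitted network
#' @param side "upper" or "lower" CI border
#' @param maxit refinement iterations
#' @return matrix fluxes x measured rates of sensitivities; re-fit
#'   failures yield NA columns
#' @export
sensitivity_to_measured <- function(fit, measured_ci, network,
                                    side = c("upper", "lower"), maxit = 40L) {
  side <- match.arg(side)
  obj <- fit$objective
  v_star <- obj$flux(fit$par)
  out <- matrix(NA_real_, length(v_star), nrow(measured_ci),
                dimnames = list(names(v_star), measured_ci$rate))
  for (k in seq_len(nrow(measured_ci))) {
    rate <- measured_ci$rate[k]
    m <- network$measured[[rate]]
    if (is.null(m)) stop("unknown measured rate: ", rate)
    v_m0 <- m$value
    v_m1 <- if (side == "upper") measured_ci$hi[k] else measured_ci$lo[k]
    if (!is.finite(v_m1) || v_m1 == v_m0) next
    net2 <- network
    net2$measured[[rate]]$value <- v_m1
    obj2 <- make_objective(net2, fit$data, params = obj$params,
                           fixed = fit$fixed,
                           experiment = fit$experiment %||% default_experiment(),
                           rtol = fit$config$rtol)
    ref <- try(refine_local(obj2, fit$par, maxit = maxit), silent = TRUE)
    if (inherits(ref, "try-error")) next
    v_new <- obj2$flux(ref$par)
    rel_m <- (v_m1 - v_m0) / v_m0
    rel_e <- (v_new - v_star) / ifelse(abs(v_star) > 1e-9, v_star, NA)
    out[, k] <- rel_e / rel_m
  }
  out
}

#' Sensitivity of the objective to the fitted parameters
#'
#' Mean normalized deviation of the SSQD over random relative
#' perturbations of each parameter around the estimate:
#' SensSSQD = mean[ (dSSQD / SSQD*) / |dp / p*| ].
#'
#' @param fit an `instcho_fit`
#' @param n_perturb perturbations per parameter
#' @param magnitude maximum relative perturbation (default 5%)
#' @param seed RNG seed
#' @return named vector of sensitivities
#' @export
sensitivity_of_objective <- function(fit, n_perturb = 100L,
                                     magnitude = 0.05, seed = 1L) {
  obj <- fit$objective
  set.seed(seed)
  out <- setNames(numeric(length(obj$params)), obj$params)
  for (i in seq_along(obj$params)) {
    est <- fit$par[[i]]
    if (abs(est) < 1e-12) { out[i] <- 0; next }
    vals <- numeric(n_perturb)
    for (k in seq_len(n_perturb)) {
      rel <- runif(1, -magnitude, magnitude)
      th <- fit$par
      th[i] <- min(max(est * (1 + rel), obj$lb[[i]]), obj$ub[[i]])
      rel_eff <- (th[i] - est) / est
      if (abs(rel_eff) < 1e-12) { vals[k] <- 0; next }
      f <- obj$fn(th)
      vals[k] <- ((f - fit$ssqd) / fit$ssqd) / abs(rel_eff)
    }
    out[i] <- mean(vals)
  }
  out
}
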