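# Forward simulation of extracellular and intracellular isotopomer dynamics
# in a growing batch culture. The coupled stiff ODE system over all IDVs is
# integrated with deSolve on top of a compiled right-hand side; growth and
# extracellular concentrations follow their closed-form batch profiles and
# are evaluated inside the RHS (they do not depend on the labeling state).

.plan_cache <- new.env(parent = emptyenv())

#' Compile a network into a simulation plan
#'
#' Builds all isotopomer mapping matrices (forward and, for reversible
#' reactions, reverse), lays out the state vector over the tracked pools and
#' returns a handle reused by every subsequent simulation of the same
#' network topology. Plans are cached per network name.
#'
#' @param network an `instcho_network`
#' @param tracer tracer specification (fixes the constant-pool IDVs)
#' @export
build_sim_plan <- function(network, tracer = tracer_spec()) {
  key <- paste0(network$name, "|", length(network$reactions), "|",
                tracer$substrate, "|", tracer$enrichment, "|", tracer$natural)
  if (!is.null(.plan_cache[[key]])) return(.plan_cache[[key]])

  mets <- network$metabolites
  tracked <- Filter(function(m) m$role %in% c("balanced", "dynamic", "co2"), mets)
  pool_ids <- names(tracked)
  pool_of <- function(id) match(id, pool_ids)

  # raw terms in R form
  rxn_ids <- names(network$reactions)
  terms <- list()
  for (j in seq_along(network$reactions)) {
    r <- network$reactions[[j]]
    has_map <- any(vapply(c(r$substrates, r$products),
                          function(x) !is.null(x$map), TRUE))
    if (!has_map) next
    for (dir in if (r$reversible) c("forward", "reverse") else "forward") {
      tms <- build_mapping_matrices(r, mets, direction = dir,
                                    p_unlabeled = tracer$natural)
      for (tm in tms) {
        if (!tm$product %in% pool_ids) next
        terms[[length(terms) + 1L]] <- list(
          target = pool_of(tm$product) - 1L,
          rxn = j - 1L,
          dir = if (dir == "forward") 0L else 1L,
          gain = if (mets[[tm$product]]$role == "dynamic") 1L else 0L,
          w = tm$w,
          inputs = vapply(tm$inputs, pool_of, 0L) - 1L,
          M = tm$M)
      }
    }
  }

  # constant pools: tracked dynamic pools never targeted by any term, plus
  # any input pool outside the tracked set would be an error
  targeted <- unique(vapply(terms, function(t) t$target, 0L))
  ctype <- vapply(pool_ids, function(id) {
    switch(tracked[[id]]$role, balanced = 1L, co2 = 1L, dynamic = 2L)
  }, 0L)
  for (i in seq_along(pool_ids)) {
    if (ctype[i] == 2L && !((i - 1L) %in% targeted)) ctype[i] <- 0L
  }

  sizes <- vapply(pool_ids, function(id) as.integer(2^tracked[[id]]$n_carbons), 0L)
  offset <- integer(length(pool_ids))
  off <- 0L
  for (i in seq_along(pool_ids)) {
    if (ctype[i] == 0L) { offset[i] <- 0L; next }
    offset[i] <- off
    off <- off + sizes[i]
  }
  n_state <- off

  const_idv <- vector("list", length(pool_ids))
  idvs <- initial_idvs(network, tracer)
  for (i in seq_along(pool_ids)) {
    const_idv[[i]] <- if (ctype[i] == 0L) idvs[[pool_ids[i]]] else numeric(0)
  }

  spec <- list(n_state = n_state, offset = offset, size = sizes,
               ctype = ctype, const_idv = const_idv, terms = terms,
               n_rxn = length(rxn_ids))
  ptr <- sim_plan_build(spec)

  # stoichiometry rows of the dynamic pools (net production per L cell)
  dynD <- matrix(0, length(pool_ids), length(rxn_ids),
                 dimnames = list(pool_ids, rxn_ids))
  is_dyn <- function(id) id %in% pool_ids &&
    tracked[[id]]$role == "dynamic"
  for (j in seq_along(network$reactions)) {
    r <- network$reactions[[j]]
    for (s in r$substrates) if (is_dyn(s$id))
      dynD[s$id, j] <- dynD[s$id, j] - s$coef / r$scale
    for (p in r$products) if (is_dyn(p$id))
      dynD[p$id, j] <- dynD[p$id, j] + p$coef / r$scale
  }

  # exact Jacobian sparsity from the nonzero pattern of every mapping
  # matrix; each state additionally depends on itself (outflux term)
  inz_list <- list(cbind(seq_len(n_state), seq_len(n_state)))
  for (tm in terms) {
    ins <- tm$inputs + 1L
    ins <- ins[ctype[ins] != 0L]
    if (!length(ins)) next
    nz <- which(tm$M != 0, arr.ind = TRUE)
    rows <- offset[tm$target + 1L] + nz[, 1]
    if (length(tm$inputs) == 1L) {
      ip <- tm$inputs[1] + 1L
      if (ctype[ip] != 0L)
        inz_list[[length(inz_list) + 1L]] <- cbind(rows, offset[ip] + nz[, 2])
    } else {
      p1 <- tm$inputs[1] + 1L; p2 <- tm$inputs[2] + 1L
      d1 <- sizes[p1]
      i1 <- (nz[, 2] - 1L) %% d1 + 1L
      i2 <- (nz[, 2] - 1L) %/% d1 + 1L
      if (ctype[p1] != 0L)
        inz_list[[length(inz_list) + 1L]] <- cbind(rows, offset[p1] + i1)
      if (ctype[p2] != 0L)
        inz_list[[length(inz_list) + 1L]] <- cbind(rows, offset[p2] + i2)
    }
  }
  inz <- unique(do.call(rbind, inz_list))
  inz <- inz[order(inz[, 2], inz[, 1]), , drop = FALSE]

  plan <- list(ptr = ptr, pool_ids = pool_ids, sizes = sizes, offset = offset,
               inz = inz,
               ctype = ctype, n_state = n_state, dynD = dynD,
               rxn_ids = rxn_ids, tracer = tracer, idvs = idvs,
               network_name = network$name)
  .plan_cache[[key]] <- plan
  plan
}

#' Default batch-experiment description (CHO-K1-like conditions)
#'
#' Exponential growth at mu = 0.0401 1/h from 4e5 cells/mL, 10.6 um cells,
#' sampling at 1, 18, 24, 42, 48, 66 and 72 h, abiotic glutamine degradation
#' kd = 0.0033 1/h, and initial medium concentrations chosen so that no
#' substrate is depleted before the 72 h horizon (glutamine runs out just
#' after it).
#'
#' @export
default_experiment <- function() {
  list(
    growth = list(mu = 0.0401, X0 = 4e5),
    geometry = cell_geometry(10.6),
    times = c(1, 18, 24, 42, 48, 66, 72),
    t_end = 72,
    kd = c(GLN_ex = 0.0033),
    tracer = tracer_spec("GLC_ex", 0.99, 0.011),
    C0 = c(GLC_ex = 42, LAC_ex = 0.2, PYR_ex = 0.2, ALA_ex = 0.1,
           GLU_ex = 0.15, GLN_ex = 8.4, ASP_ex = 2.5, ASN_ex = 7.5,
           SER_ex = 5.5, GLY_ex = 0.15)
  )
}

#' Default intracellular pool sizes
#'
#' Small fast pools (1 mmol/L cell) for every balanced metabolite and the
#' dissolved CO2 pool; individual sizes can be overridden by name, and the
#' CO2 pool size is a fittable parameter of the non-compartmented model.
#'
#' @param network an `instcho_network`
#' @param overrides named numeric vector of pool sizes
#' @param co2_pool CO2 pool size, mmol/L cell
#' @export
default_pool_sizes <- function(network, overrides = NULL, co2_pool = 1.0) {
  ids <- names(Filter(function(m) m$role %in% c("balanced", "co2"),
                      network$metabolites))
  ps <- setNames(rep(1.0, length(ids)), ids)
  co2id <- names(Filter(function(m) m$role == "co2", network$metabolites))
  if (length(co2id)) ps[co2id] <- co2_pool
  if (!is.null(overrides)) ps[names(overrides)] <- overrides
  ps
}

# closed-form extracellular concentration for pre-checks
dyn_conc <- function(t, C0, vnet_cell, mu, Xc0, kd = 0) {
  conc_profile(t, C0, vnet_cell, mu, Xc0, kd)
}

#' Simulate the labeling time course of a batch culture
#'
#' Integrates the coupled isotopomer balances of all intracellular,
#' dissolved-CO2 and extracellular pools over the batch horizon and returns
#' the mass isotopomer distributions of the measured fragments.
#'
#' @param network an `instcho_network`
#' @param v named net-flux vector satisfying G v = 0 (from the free-flux
#'   solver)
#' @param experiment see [default_experiment()]
#' @param rev_params named overrides of reversibility-model parameters
#'   (e.g. `REV_LDH1.rev`, `REV_PYRT.rev0`, `REV_ALAT.alpha`)
#' @param pool_sizes named pool sizes (see [default_pool_sizes()])
#' @param fragments fragment table; default [default_fragments()]
#' @param times output times (h); defaults to the experiment sampling times
#' @param rtol,atol integrator tolerances (stiff solver)
#' @param full return the complete state trajectory as attribute
#' @return object of class `instcho_sim`: list with `times`, `mids` (list
#'   fragment -> time x mass matrix), `conc` (extracellular concentration
#'   table), `X` (cell density), `v`
#' @export
simulate_labeling <- function(network, v, experiment = default_experiment(),
                              rev_params = NULL, pool_sizes = NULL,
                              fragments = default_fragments(),
                              times = NULL, rtol = 1e-6, atol = 1e-8,
                              full = FALSE) {
  plan <- build_sim_plan(network, experiment$tracer)
  if (is.null(times)) times <- experiment$times
  if (is.null(pool_sizes)) pool_sizes <- default_pool_sizes(network)

  rxn_ids <- plan$rxn_ids
  stopifnot(setequal(names(v), rxn_ids))
  v <- v[rxn_ids]
  irrev <- vapply(network$reactions, function(r) !r$reversible, TRUE)
  if (any(v[irrev] < -1e-6))
    stop("negative net flux on irreversible reaction(s): ",
         paste(rxn_ids[irrev & v < -1e-6], collapse = ", "))

  rms <- reaction_rev_models(network, rev_params)
  revkind <- integer(length(rxn_ids))
  revp1 <- revp2 <- numeric(length(rxn_ids))
  for (j in seq_along(rxn_ids)) {
    m <- rms[[rxn_ids[j]]]
    if (is.null(m)) next
    if (m$kind == "constant") { revkind[j] <- 1L; revp1[j] <- m$rev }
    else if (m$kind == "hyperbolic") { revkind[j] <- 2L; revp1[j] <- m$rev0; revp2[j] <- m$eps }
    else { revkind[j] <- 3L; revp1[j] <- m$alpha; revp2[j] <- m$beta }
    if (revp1[j] < 0)
      stop("negative reversibility for reaction ", rxn_ids[j])
  }

  mu <- experiment$growth$mu
  Xc0 <- cell_volume_concentration(experiment$growth$X0, experiment$geometry)
  t_end <- max(times)

  # per-pool concentration parameter and dynamic-rate vectors
  pool_par <- numeric(length(plan$pool_ids))
  dyn_vnet <- dyn_kd <- numeric(length(plan$pool_ids))
  vd_all <- as.numeric(plan$dynD %*% v)
  for (i in seq_along(plan$pool_ids)) {
    id <- plan$pool_ids[i]
    if (plan$ctype[i] == 2L) {
      if (!id %in% names(experiment$C0))
        stop("no initial concentration for dynamic pool ", id)
      pool_par[i] <- experiment$C0[[id]]
      dyn_vnet[i] <- vd_all[i]
      dyn_kd[i] <- if (id %in% names(experiment$kd)) experiment$kd[[id]] else 0
      tt <- seq(0, t_end, length.out = 200)
      cc <- dyn_conc(tt, pool_par[i], dyn_vnet[i], mu, Xc0, dyn_kd[i])
      if (any(cc <= 0)) {
        tdep <- tt[which(cc <= 0)[1]]
        stop("extracellular pool ", id, " depleted at t = ",
             signif(tdep, 4), " h, before the simulation horizon (",
             t_end, " h); truncate the time grid")
      }
    } else if (plan$ctype[i] == 1L) {
      pool_par[i] <- pool_sizes[[id]]
    }
  }

  sim_plan_set_params(plan$ptr, v, revkind, revp1, revp2,
                      pool_par, dyn_vnet, dyn_kd, mu, Xc0)

  y0 <- numeric(plan$n_state)
  for (i in seq_along(plan$pool_ids)) {
    if (plan$ctype[i] == 0L) next
    y0[plan$offset[i] + seq_len(plan$sizes[i])] <- plan$idvs[[plan$pool_ids[i]]]
  }

  ptr <- plan$ptr
  f <- function(t, y, parms) list(sim_rhs(ptr, t, y))
  out_times <- sort(unique(c(0, times)))
  # strongly cyclic flux regimes (large exchange loops) put Jacobian
  # eigenvalues close to the imaginary axis, where the high-order BDF
  # formulas lose stability and the step size collapses; retry at order 3
  # (stability region covers most of the left half-plane) if order 5 fails
  integrate_once <- function(maxord, maxsteps) {
    deSolve::lsodes(y = y0, times = out_times, func = f, parms = NULL,
                    rtol = rtol, atol = atol, sparsetype = "sparseusr",
                    inz = plan$inz, maxsteps = maxsteps, maxord = maxord,
                    lrw = 40L * plan$n_state + 8L * nrow(plan$inz))
  }
  sol <- integrate_once(5L, 2500)
  if (attr(sol, "istate")[1] < 0) sol <- integrate_once(3L, 10000)
  if (attr(sol, "istate")[1] < 0)
    stop("stiff ODE integration failed (istate ",
         attr(sol, "istate")[1], "); see diagnostics(sol)")
  keep <- match(times, out_times)
  Y <- sol[keep, -1, drop = FALSE]

  mids <- list()
  for (k in seq_len(nrow(fragments))) {
    id <- paste0(fragments$metabolite[k], "_ex")
    i <- match(id, plan$pool_ids)
    if (is.na(i)) stop("fragment pool not in network: ", id)
    nb <- fragments$n_backbone[k]
    mat <- matrix(0, length(times), nb + 1L,
                  dimnames = list(NULL, paste0("m", 0:nb)))
    for (ti in seq_len(length(times))) {
      idv <- if (plan$ctype[i] == 0L) plan$idvs[[id]]
             else Y[ti, plan$offset[i] + seq_len(plan$sizes[i])]
      mat[ti, ] <- idv_to_mid(idv)
    }
    mids[[fragments$fragment[k]]] <- mat
  }

  conc <- data.frame(time_h = times)
  for (i in seq_along(plan$pool_ids)) {
    if (plan$ctype[i] != 2L) next
    conc[[plan$pool_ids[i]]] <- dyn_conc(times, pool_par[i], dyn_vnet[i],
                                         mu, Xc0, dyn_kd[i])
  }
  res <- structure(list(times = times, mids = mids, conc = conc,
                        X = experiment$growth$X0 * exp(mu * times),
                        v = v), class = "instcho_sim")
  if (full) attr(res, "state") <- sol
  res
}

#' @export
print.instcho_sim <- function(x, ...) {
  cat("labeling simulation:", length(x$mids), "fragments at",
      length(x$times), "times (t =", paste(x$times, collapse = ", "), "h)\n")
  invisible(x)
}

#' Flatten simulated MIDs to a tidy table
#'
#' @param sim an `instcho_sim`
#' @return data.frame fragment, time_h, m0..m6
#' @export
sim_to_mid_table <- function(sim) {
  rows <- list()
  for (fr in names(sim$mids)) {
    m <- sim$mids[[fr]]
    df <- data.frame(fragment = fr, time_h = sim$times)
    for (k in seq_len(ncol(m))) df[[colnames(m)[k]]] <- m[, k]
    rows[[fr]] <- df
  }
  out <- do.call(rbind, lapply(rows, function(d) {
    for (k in paste0("m", 0:6)) if (!k %in% names(d)) d[[k]] <- NA_real_
    d[, c("fragment", "time_h", paste0("m", 0:6))]
  }))
  rownames(out) <- NULL
  out
}
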