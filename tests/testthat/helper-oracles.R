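# Independent oracles used by the tests. These deliberately avoid the
# package's own linear-algebra and IMM code paths.

# ---- exact rational rank (fraction Gaussian elimination) -------------------

gcd2 <- function(a, b) { a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }; a }

# rank of a matrix with rational entries given as num/den integer matrices
rational_rank <- function(num, den = NULL) {
  if (is.null(den)) den <- matrix(1, nrow(num), ncol(num))
  stopifnot(all(den != 0), all(num == round(num)), all(den == round(den)))
  m <- nrow(num); n <- ncol(num)
  reduce <- function(p, q) {
    if (p == 0) return(c(0, 1))
    g <- gcd2(p, q); s <- if (q < 0) -1 else 1
    c(s * p / g, s * q / g)
  }
  rank <- 0L
  row <- 1L
  for (col in seq_len(n)) {
    piv <- which(num[row:m, col] != 0)
    if (!length(piv)) next
    i <- piv[1] + row - 1L
    if (i != row) { num[c(i, row), ] <- num[c(row, i), ]; den[c(i, row), ] <- den[c(row, i), ] }
    pn <- num[row, col]; pd <- den[row, col]
    for (r in setdiff(row:m, row)) {
      if (num[r, col] == 0) next
      # row_r <- row_r - (a_r/p) * row_row  where a_r = num/den at (r,col)
      fn <- num[r, col] * pd; fd <- den[r, col] * pn
      for (cc in seq_len(n)) {
        # x - (fn/fd)*(y)  with x = num[r,cc]/den[r,cc], y = num[row,cc]/den[row,cc]
        xn <- num[r, cc]; xd <- den[r, cc]
        yn <- num[row, cc]; yd <- den[row, cc]
        rn <- xn * fd * yd - fn * yn * xd
        rd <- xd * fd * yd
        v <- reduce(rn, rd)
        if (abs(v[1]) > 2^48 || abs(v[2]) > 2^48) stop("rational overflow")
        num[r, cc] <- v[1]; den[r, cc] <- v[2]
      }
    }
    rank <- rank + 1L
    row <- row + 1L
    if (row > m) break
  }
  rank
}

# combined [G; measured rows] system of a network, as exact rationals
# (stoichiometries are integers except the 5/3 PPP column; scale by the
# reaction 'scale' denominators)
rational_system <- function(net) {
  bal <- names(Filter(function(m) m$role == "balanced", net$metabolites))
  rxns <- net$reactions
  num <- matrix(0, length(bal) + length(net$measured), length(rxns),
                dimnames = list(c(bal, names(net$measured)), names(rxns)))
  den <- matrix(1, nrow(num), ncol(num),
                dimnames = dimnames(num))
  for (j in seq_along(rxns)) {
    r <- rxns[[j]]
    sc <- r$scale
    stopifnot(sc == round(sc))
    for (s in r$substrates) if (s$id %in% bal) {
      stopifnot(s$coef == round(s$coef))
      num[s$id, j] <- num[s$id, j] * sc - s$coef * den[s$id, j]
      den[s$id, j] <- den[s$id, j] * sc
    }
    for (p in r$products) if (p$id %in% bal) {
      stopifnot(p$coef == round(p$coef))
      num[p$id, j] <- num[p$id, j] * sc + p$coef * den[p$id, j]
      den[p$id, j] <- den[p$id, j] * sc
    }
  }
  for (i in seq_along(net$measured))
    num[length(bal) + i, net$measured[[i]]$reactions] <- 1
  list(num = num, den = den)
}

# ---- brute-force isotopomer propagation ------------------------------------

# Enumerates every joint labeling state of all mapped substrate instances
# (probability = product of their IDV entries) and every unlabeled-source /
# scrambling branch, and accumulates the product-isotopomer distribution for
# one mapped product instance. prod_idx indexes the mapped products.
brute_force_product_idv <- function(reaction, mets, sub_idvs, prod_idx,
                                    p_unlabeled = 0.011) {
  has_map <- function(x) !is.null(x$map)
  subs <- Filter(has_map, reaction$substrates)
  prods <- Filter(has_map, reaction$products)
  p <- prods[[prod_idx]]
  if (mets[[p$id]]$role %in% c("sink", "gas")) return(NULL)
  np <- mets[[p$id]]$n_carbons
  # letter -> (substrate instance, carbon position)
  src <- list()
  for (i in seq_along(subs)) {
    chars <- strsplit(subs[[i]]$map, "")[[1]]
    for (k in seq_along(chars)) src[[chars[k]]] <- c(i, k)
  }
  ns <- vapply(subs, function(s) mets[[s$id]]$n_carbons, 0L)
  dist <- numeric(2^np)
  n_joint <- prod(2^ns)
  alts <- lapply(p$map, function(m) strsplit(m, "")[[1]])
  for (joint in 0:(n_joint - 1L)) {
    # decode instance states
    states <- integer(length(subs)); rem <- joint
    for (i in seq_along(subs)) {
      states[i] <- rem %% 2^ns[i]; rem <- rem %/% 2^ns[i]
    }
    pr <- 1
    for (i in seq_along(subs)) pr <- pr * sub_idvs[[i]][states[i] + 1L]
    if (pr == 0) next
    for (a in alts) {
      stars <- which(a == "*")
      base <- 0L
      for (k in seq_along(a)) {
        if (a[k] == "*") next
        e <- src[[a[k]]]
        if (bitwAnd(states[e[1]], bitwShiftL(1L, e[2] - 1L)) != 0L)
          base <- base + bitwShiftL(1L, k - 1L)
      }
      if (!length(stars)) {
        dist[base + 1L] <- dist[base + 1L] + pr / length(alts)
      } else {
        for (sub in 0:(2^length(stars) - 1L)) {
          st <- base; w <- pr / length(alts)
          for (q in seq_along(stars)) {
            if (bitwAnd(sub, bitwShiftL(1L, q - 1L)) != 0L) {
              st <- st + bitwShiftL(1L, stars[q] - 1L); w <- w * p_unlabeled
            } else w <- w * (1 - p_unlabeled)
          }
          dist[st + 1L] <- dist[st + 1L] + w
        }
      }
    }
  }
  dist
}

# ---- toy networks ----------------------------------------------------------

write_net <- function(lines) {
  f <- tempfile(fileext = ".net")
  writeLines(lines, f)
  f
}

# one balanced pool A fed by labeled substrate and an unlabeled dilution
# flux, exporting reversibly to P_ex; 1 free flux (dil) + 1 reversibility
toy_branch_net <- function(upt = 100, rev = 1.0) {
  write_net(c(
    "name toy_branch",
    "met S_ex 2 extracellular dynamic",
    "met U_ex 2 extracellular source",
    "met A 2 cytosolic balanced",
    "met P_ex 2 extracellular dynamic",
    sprintf("rev REV_P constant rev=%g", rev),
    "rxn upt: S_ex (ab) -> A (ab)",
    "rxn dil: U_ex -> A (**)",
    "rxn out: A (ab) -> P_ex (ab), rev_model=REV_P",
    sprintf("measure upt = %g", upt),
    "prefer_free dil"))
}

toy_fragments <- function() {
  data.frame(fragment = "P", metabolite = "P", mz = 0L, n_backbone = 2L,
             C = 2L, H = 0L, N = 0L, O = 0L, Si = 0L,
             stringsAsFactors = FALSE)
}

toy_experiment <- function(pool_A = 1.0) {
  list(growth = list(mu = 0.0401, X0 = 4e5),
       geometry = cell_geometry(10.6),
       times = c(1, 18, 24, 42, 48, 66, 72),
       t_end = 72,
       kd = c(),
       tracer = tracer_spec("S_ex", 0.99, 0.011),
       C0 = c(S_ex = 40, P_ex = 5))
}

# measured pool under net uptake: its extracellular labeling is carried
# entirely by the reverse exchange flux, so the reversibility is strongly
# identifiable from the labeling time course (dilution sets the plateau)
toy_uptake_net <- function(upt = 100, pupt = 20, rev = 1.0) {
  write_net(c(
    "name toy_uptake",
    "met S_ex 2 extracellular dynamic",
    "met U_ex 2 extracellular source",
    "met A 2 cytosolic balanced",
    "met P_ex 2 extracellular dynamic",
    "met BM 0 none sink",
    sprintf("rev REV_P constant rev=%g", rev),
    "rxn upt: S_ex (ab) -> A (ab)",
    "rxn pupt: P_ex (ab) -> A (ab), rev_model=REV_P",
    "rxn dil: U_ex -> A (**)",
    "rxn drain: A -> BM",
    sprintf("measure upt = %g", upt),
    sprintf("measure pupt = %g", pupt),
    "prefer_free dil"))
}

toy_scenario <- function(dil = 30, rev = 1.0, mid_sd = 0.005, seed = 1L) {
  net <- load_network(toy_uptake_net(rev = rev))
  scn <- cho_default_scenario(network = net, free = c(dil = dil),
                              experiment = toy_experiment(),
                              mid_sd = mid_sd, seed = seed)
  scn
}

# generate toy measurements and assemble them for fitting
toy_data <- function(scn, seed = 1L) {
  gen <- generate_toy(scn, seed)
  mid_data(gen$mids, toy_fragments())
}

generate_toy <- function(scn, seed = 1L) {
  set.seed(seed)
  sim <- simulate_labeling(scn$network, scn$v, experiment = scn$experiment,
                           fragments = toy_fragments())
  rows <- list()
  for (ti in seq_along(sim$times)) {
    x <- sim$mids$P[ti, ]
    if (scn$mid_sd > 0) {
      x <- x + rnorm(length(x), 0, scn$mid_sd)
      x[x < 0] <- 0; x <- x / sum(x)
    }
    rows[[ti]] <- data.frame(fragment = "P", time_h = sim$times[ti],
                             m0 = x[1], m1 = x[2], m2 = x[3],
                             sd0 = scn$mid_sd, sd1 = scn$mid_sd,
                             sd2 = scn$mid_sd)
  }
  list(mids = do.call(rbind, rows), sim = sim)
}
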