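#' @useDynLib instcho, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats lm coef vcov qchisq qnorm rnorm runif setNames optimize
#' @importFrom utils read.csv write.csv head tail
NULL

VALID_ROLES <- c("balanced", "dynamic", "source", "sink", "gas", "co2")
VALID_COMPARTMENTS <- c("extracellular", "cytosolic", "mitochondrial", "none")

#' Load a metabolic network from a text config
#'
#' Parses the line-oriented network dialect used by the bundled CHO-K1
#' fixtures: `met` lines declare metabolites (id, carbon count, compartment,
#' role), `rev` lines declare reversibility models, `rxn` lines declare
#' reactions with carbon atom transitions in letter notation
#' (`A (abc) + B (de) -> C (abde) + D (c)`), `measure` lines fix
#' experimentally determined rates, and `prefer_free` names the reactions
#' preferred as free-flux coordinates.
#'
#' Atom maps use one letter per substrate carbon; `*` marks a product carbon
#' supplied by an unlabeled source; alternatives separated by `|` are
#' equiprobable scrambled transitions (e.g. through the symmetric
#' succinate/fumarate pool). A reaction may carry `scale=k` when its atom map
#' is written over k molecule instances but its flux is accounted per single
#' molecule (used for the lumped oxidative PPP where 3 G6P yield 5 PG).
#'
#' @param path path to a `.net` file (see
#'   `system.file("extdata", "cho_k1_compartmented.net", package = "instcho")`)
#' @return an object of class `instcho_network`
#' @export
load_network <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  mets <- list()
  revmodels <- list()
  reactions <- list()
  measured <- list()
  prefer_free <- character()
  net_name <- "network"

  for (ln in lines) {
    kw <- sub("\\s.*$", "", ln)
    body <- trimws(sub("^\\S+\\s*", "", ln))
    switch(kw,
      name = { net_name <- body },
      met = {
        f <- strsplit(body, "\\s+")[[1]]
        if (length(f) != 4L) stop("malformed met line: ", ln)
        mets[[f[1]]] <- list(id = f[1], n_carbons = as.integer(f[2]),
                             compartment = f[3], role = f[4])
      },
      rev = { revmodels[[sub("\\s.*$", "", body)]] <- parse_rev_model(body) },
      rxn = { r <- parse_reaction(body); reactions[[r$id]] <- r },
      measure = {
        m <- parse_measure(body)
        measured[[m$id]] <- m
      },
      prefer_free = { prefer_free <- strsplit(body, "\\s+")[[1]] },
      stop("unknown keyword '", kw, "' in network file")
    )
  }

  net <- structure(list(
    name = net_name,
    metabolites = mets,
    reactions = reactions,
    rev_models = revmodels,
    measured = measured,
    prefer_free = prefer_free
  ), class = "instcho_network")
  validate_network(net)
  net
}

parse_rev_model <- function(body) {
  f <- strsplit(body, "\\s+")[[1]]
  id <- f[1]; kind <- f[2]
  kv <- parse_kv(f[-(1:2)])
  m <- switch(kind,
    constant = list(kind = "constant", rev = kv$rev),
    hyperbolic = list(kind = "hyperbolic", rev0 = kv$rev0, eps = kv$eps),
    exponential = list(kind = "exponential", alpha = kv$alpha, beta = kv$beta),
    stop("unknown reversibility model kind: ", kind))
  m$id <- id
  m
}

parse_kv <- function(parts) {
  kv <- list()
  for (p in parts) {
    s <- strsplit(p, "=")[[1]]
    kv[[s[1]]] <- suppressWarnings(as.numeric(s[2]))
  }
  kv
}

# One side of a reaction: "2 A (abc|cba) + B" -> list of instances
parse_side <- function(txt) {
  terms <- strsplit(txt, "\\+(?![^()]*\\))", perl = TRUE)[[1]]
  out <- list()
  for (tm in terms) {
    tm <- trimws(tm)
    if (!nzchar(tm)) next
    coef <- 1
    cm <- regmatches(tm, regexec("^([0-9.]+(?:/[0-9.]+)?)\\s+", tm))[[1]]
    if (length(cm) == 2L) {
      coef <- eval(parse(text = cm[2]))
      tm <- trimws(sub("^[0-9./]+\\s+", "", tm))
    }
    map <- NULL
    mm <- regmatches(tm, regexec("^(\\S+)\\s*\\(([^)]*)\\)$", tm))[[1]]
    if (length(mm) == 3L) {
      id <- mm[2]
      map <- strsplit(mm[3], "|", fixed = TRUE)[[1]]
    } else {
      id <- trimws(tm)
    }
    out[[length(out) + 1L]] <- list(id = id, coef = coef, map = map)
  }
  out
}

parse_reaction <- function(body) {
  id <- trimws(sub(":.*$", "", body))
  rest <- trimws(sub("^[^:]+:", "", body))
  opts <- list(reversible = FALSE, rev_model = NA_character_, scale = 1,
               lb = NA_real_, ub = NA_real_)
  # trailing options after final comma(s)
  while (grepl(",", rest)) {
    tailtxt <- trimws(sub("^.*,", "", rest))
    if (grepl("^(reversible|rev_model=|scale=|bounds=)", tailtxt)) {
      rest <- trimws(sub(",[^,]*$", "", rest))
      if (tailtxt == "reversible") opts$reversible <- TRUE
      else if (startsWith(tailtxt, "rev_model=")) {
        opts$reversible <- TRUE
        opts$rev_model <- sub("^rev_model=", "", tailtxt)
      } else if (startsWith(tailtxt, "scale=")) {
        opts$scale <- as.numeric(sub("^scale=", "", tailtxt))
      } else if (startsWith(tailtxt, "bounds=")) {
        b <- as.numeric(strsplit(sub("^bounds=", "", tailtxt), ":")[[1]])
        opts$lb <- b[1]; opts$ub <- b[2]
      }
    } else break
  }
  sides <- strsplit(rest, "->", fixed = TRUE)[[1]]
  if (length(sides) != 2L) stop("reaction '", id, "': missing '->'")
  list(id = id,
       substrates = parse_side(sides[1]),
       products = parse_side(sides[2]),
       reversible = opts$reversible,
       rev_model = opts$rev_model,
       scale = opts$scale,
       lb = opts$lb, ub = opts$ub)
}

parse_measure <- function(body) {
  # "glc_upt = 371.0"  or  "lac_prod : ldh1 + ldh2 = 289.4"
  val <- as.numeric(trimws(sub("^.*=", "", body)))
  lhs <- trimws(sub("=.*$", "", body))
  if (grepl(":", lhs)) {
    id <- trimws(sub(":.*$", "", lhs))
    rxns <- trimws(strsplit(sub("^[^:]+:", "", lhs), "+", fixed = TRUE)[[1]])
  } else {
    id <- lhs
    rxns <- lhs
  }
  list(id = id, reactions = rxns, value = val)
}

#' @export
print.instcho_network <- function(x, ...) {
  nb <- sum(vapply(x$metabolites, function(m) m$role == "balanced", TRUE))
  cat("instcho network '", x$name, "': ",
      length(x$reactions), " reactions, ", nb, " balanced metabolites, ",
      length(x$measured), " measured rates\n", sep = "")
  invisible(x)
}

validate_network <- function(net) {
  mets <- net$metabolites
  for (m in mets) {
    if (m$n_carbons < 0) stop("metabolite ", m$id, ": negative carbon count")
    if (!m$role %in% VALID_ROLES) stop("metabolite ", m$id, ": bad role ", m$role)
    if (!m$compartment %in% VALID_COMPARTMENTS)
      stop("metabolite ", m$id, ": bad compartment ", m$compartment)
  }
  for (r in net$reactions) {
    for (s in c(r$substrates, r$products)) {
      if (is.null(mets[[s$id]]))
        stop("reaction ", r$id, ": unknown metabolite ", s$id)
    }
    validate_atom_map(r, mets)
    if (r$reversible && !is.na(r$rev_model) && is.null(net$rev_models[[r$rev_model]]))
      stop("reaction ", r$id, ": unknown rev model ", r$rev_model)
  }
  for (m in net$measured) {
    missing <- setdiff(m$reactions, names(net$reactions))
    if (length(missing))
      stop("measured rate ", m$id, ": unknown reaction(s) ", paste(missing, collapse = ", "))
  }
  invisible(net)
}

# Carbon conservation: each substrate-instance letter appears exactly once
# across product maps (within each scrambling alternative); every product
# carbon traces to a substrate letter or '*' (unlabeled source feed).
validate_atom_map <- function(r, mets) {
  has_map <- function(x) !is.null(x$map)
  sub_mapped <- Filter(has_map, r$substrates)
  prod_mapped <- Filter(has_map, r$products)
  if (length(sub_mapped) == 0L && length(prod_mapped) == 0L) {
    # stoichiometry-only (biomass-type drain): all products must be sinks
    bad <- Filter(function(p) mets[[p$id]]$role != "sink", r$products)
    if (length(bad))
      stop("reaction ", r$id, ": no atom map but product ",
           bad[[1]]$id, " is not a sink")
    return(invisible(TRUE))
  }
  sub_letters <- character()
  for (s in sub_mapped) {
    if (length(s$map) != 1L)
      stop("reaction ", r$id, ": scrambling alternatives only allowed on products")
    if (nchar(s$map) != mets[[s$id]]$n_carbons)
      stop("reaction ", r$id, ": atom map '", s$map, "' of ", s$id,
           " has ", nchar(s$map), " carbons, metabolite has ",
           mets[[s$id]]$n_carbons)
    sub_letters <- c(sub_letters, strsplit(s$map, "")[[1]])
  }
  if (anyDuplicated(sub_letters))
    stop("reaction ", r$id, ": duplicate substrate carbon letter")
  used <- NULL
  for (p in prod_mapped) {
    nlet <- unique(nchar(p$map))
    if (length(nlet) != 1L || nlet != mets[[p$id]]$n_carbons)
      stop("reaction ", r$id, ": atom map of product ", p$id,
           " does not match its carbon count (", mets[[p$id]]$n_carbons, ")")
    alts <- lapply(p$map, function(m) strsplit(m, "")[[1]])
    lets <- setdiff(alts[[1]], "*")
    for (a in alts[-1]) {
      if (!setequal(setdiff(a, "*"), lets))
        stop("reaction ", r$id, ": scrambling alternatives of ", p$id,
             " use different substrate carbons")
    }
    bad <- setdiff(lets, sub_letters)
    if (length(bad))
      stop("reaction ", r$id, ": product carbon source '", bad[1],
           "' not among substrate carbons")
    used <- c(used, lets)
  }
  if (anyDuplicated(used))
    stop("reaction ", r$id, ": substrate carbon used twice across products")
  lost <- setdiff(sub_letters, used)
  if (length(lost))
    stop("reaction ", r$id, ": substrate carbons ",
         paste(lost, collapse = ""), " are not transferred to any product ",
         "(declare an explicit sink product for carbon losses)")
  # products with no map must be sinks or sources
  for (p in Filter(function(x) is.null(x$map), r$products)) {
    if (!mets[[p$id]]$role %in% c("sink"))
      stop("reaction ", r$id, ": product ", p$id, " lacks an atom map")
  }
  invisible(TRUE)
}

balanced_ids <- function(net) {
  names(Filter(function(m) m$role == "balanced", net$metabolites))
}

dynamic_ids <- function(net) {
  names(Filter(function(m) m$role == "dynamic", net$metabolites))
}

#' Stoichiometric matrix over balanced metabolites
#'
#' Column j holds the net stoichiometric coefficients of reaction j
#' (divided by its `scale`) over balanced intracellular metabolites only;
#' extracellular, source and sink pools are excluded from the rows.
#'
#' @param network an `instcho_network`
#' @return numeric matrix of dimension m_balanced x n_reactions
#' @export
build_stoichiometry <- function(network) {
  bal <- balanced_ids(network)
  rxns <- network$reactions
  G <- matrix(0, length(bal), length(rxns),
              dimnames = list(bal, names(rxns)))
  for (j in seq_along(rxns)) {
    r <- rxns[[j]]
    for (s in r$substrates) if (s$id %in% bal)
      G[s$id, j] <- G[s$id, j] - s$coef / r$scale
    for (p in r$products) if (p$id %in% bal)
      G[p$id, j] <- G[p$id, j] + p$coef / r$scale
  }
  G
}

# Measured-rate constraint matrix: one row per measured rate, value vector.
measured_system <- function(network, values = NULL) {
  rxn_ids <- names(network$reactions)
  ms <- network$measured
  E <- matrix(0, length(ms), length(rxn_ids),
              dimnames = list(names(ms), rxn_ids))
  phi <- numeric(length(ms))
  for (i in seq_along(ms)) {
    E[i, ms[[i]]$reactions] <- 1
    phi[i] <- ms[[i]]$value
  }
  names(phi) <- names(ms)
  if (!is.null(values)) {
    stopifnot(all(names(values) %in% names(phi)))
    phi[names(values)] <- values
  }
  list(E = E, phi = phi)
}

#' Flux bounds for every reaction
#'
#' Defaults: irreversible reactions are bounded to non-negative net flux,
#' reversible ones are two-sided; per-reaction `bounds=` in the config win.
#'
#' @param network an `instcho_network`
#' @param vmax default magnitude bound, mmol/(L cell x h)
#' @return data.frame with columns reaction, lb, ub
#' @export
flux_bounds <- function(network, vmax = 2000) {
  rxns <- network$reactions
  lb <- vapply(rxns, function(r) if (!is.na(r$lb)) r$lb else if (r$reversible) -vmax else 0, 0)
  ub <- vapply(rxns, function(r) if (!is.na(r$ub)) r$ub else vmax, 0)
  data.frame(reaction = names(rxns), lb = lb, ub = ub, row.names = NULL)
}

#' Partition fluxes into free and dependent coordinates
#'
#' Combines the stoichiometric balance G v = 0 with the measured-rate rows
#' and extracts a free-flux parameterization: the non-pivot columns of the
#' reduced system are the free fluxes and the returned solver maps any
#' assignment of free fluxes (plus measured-rate values) to the full net flux
#' vector. Pivoting prefers to keep the reactions named in the config's
#' `prefer_free` line as free coordinates, which makes the parameterization
#' deterministic and reproducible.
#'
#' @param network an `instcho_network`
#' @param tol rank tolerance for the row-echelon elimination
#' @return list with `free` (reaction ids), `dependent`, `rank`, `n_free`,
#'   and `solver(free_values, measured_values = NULL)` returning the full
#'   named net-flux vector. Bound violations are reported via attributes by
#'   `check_flux_vector()`, never silently clipped.
#' @export
extract_free_fluxes <- function(network, tol = 1e-9) {
  G <- build_stoichiometry(network)
  msys <- measured_system(network)
  A <- rbind(G, msys$E)
  rxn_ids <- colnames(A)
  n <- ncol(A)

  # column order: preferred-free last so pivoting consumes the others first
  pref <- intersect(network$prefer_free, rxn_ids)
  ord <- c(setdiff(rxn_ids, pref), pref)
  piv_cols <- rref_pivots(A[, ord, drop = FALSE], tol)
  dep <- ord[piv_cols]
  free <- setdiff(rxn_ids, dep)
  rk <- length(dep)

  Ad <- A[, dep, drop = FALSE]
  Af <- A[, free, drop = FALSE]
  qrAd <- qr(Ad)
  if (qrAd$rank < length(dep)) stop("internal: dependent block rank-deficient")

  b0 <- c(rep(0, nrow(G)), msys$phi)
  solver <- function(free_values, measured_values = NULL) {
    stopifnot(length(free_values) == length(free))
    if (!is.null(names(free_values)) && all(free %in% names(free_values)))
      free_values <- free_values[free]
    b <- b0
    if (!is.null(measured_values)) {
      idx <- match(names(measured_values), names(msys$phi))
      if (anyNA(idx)) stop("unknown measured rate: ",
                           paste(names(measured_values)[is.na(idx)], collapse = ", "))
      b[nrow(G) + idx] <- measured_values
    }
    rhs <- b - Af %*% free_values
    vd <- qr.coef(qrAd, rhs)
    v <- setNames(numeric(n), rxn_ids)
    v[dep] <- vd
    v[free] <- free_values
    resid <- max(abs(A %*% v - b))
    if (resid > 1e-6 * max(1, max(abs(v))))
      stop("measured rates inconsistent with G.v=0 (residual ", signif(resid, 3), ")")
    v
  }

  list(free = free, dependent = dep, rank = rk, n_free = n - rk,
       solver = solver, G = G, measured = msys)
}

# Pivot columns of the row-reduced echelon form (partial pivoting by max
# absolute entry within each column, columns processed left to right).
rref_pivots <- function(A, tol = 1e-9) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  piv <- integer(0)
  row <- 1L
  scale <- max(abs(A), 1)
  for (col in seq_len(n)) {
    if (row > m) break
    i <- which.max(abs(A[row:m, col])) + row - 1L
    if (abs(A[i, col]) <= tol * scale) next
    if (i != row) A[c(i, row), ] <- A[c(row, i), ]
    A[row, ] <- A[row, ] / A[row, col]
    others <- setdiff(seq_len(m), row)
    A[others, ] <- A[others, ] - outer(A[others, col], A[row, ])
    piv <- c(piv, col)
    row <- row + 1L
  }
  piv
}

#' Check a net flux vector against the network bounds
#'
#' @param network an `instcho_network`
#' @param v named net-flux vector
#' @param vmax default bound magnitude passed to [flux_bounds()]
#' @return TRUE invisibly if feasible, otherwise a data.frame of violations
#'   (reaction, value, lb, ub) with a warning
#' @export
check_flux_vector <- function(network, v, vmax = 2000) {
  b <- flux_bounds(network, vmax)
  bad <- which(v[b$reaction] < b$lb - 1e-9 | v[b$reaction] > b$ub + 1e-9)
  if (length(bad)) {
    viol <- data.frame(reaction = b$reaction[bad], value = v[b$reaction][bad],
                       lb = b$lb[bad], ub = b$ub[bad], row.names = NULL)
    warning("flux bounds violated for: ", paste(viol$reaction, collapse = ", "))
    return(viol)
  }
  invisible(TRUE)
}

#' Validation report for a network
#'
#' @param network an `instcho_network`
#' @param path optional path to write the report as JSON
#' @return list with metabolite/reaction tallies, rank and free fluxes
#' @export
network_report <- function(network, path = NULL) {
  ff <- extract_free_fluxes(network)
  rep <- list(
    name = network$name,
    n_reactions = length(network$reactions),
    n_balanced_metabolites = length(balanced_ids(network)),
    n_measured = length(network$measured),
    rank = ff$rank,
    n_free = ff$n_free,
    free_fluxes = ff$free,
    balanced_metabolites = balanced_ids(network)
  )
  if (!is.null(path))
    jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE)
  rep
}

#' Path to a bundled network fixture
#'
#' @param which "compartmented" or "noncompartmented"
#' @return file path
#' @export
cho_network_path <- function(which = c("compartmented", "noncompartmented")) {
  which <- match.arg(which)
  system.file("extdata", paste0("cho_k1_", which, ".net"),
              package = "instcho", mustWork = TRUE)
}
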